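# Namespace conversion: policies, fates, and agreement with the dense
# brute-force reference.

simple_matrix <- function(values, genes, obs = paste0("c", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, obs)
  expression_matrix(values)
}

test_that("a bijective table renames rows and conserves every count", {
  withr::local_seed(21)
  m <- rand_count_matrix(15, 6)
  tab <- ortholog_table(data.frame(source_gene = rownames(m),
                                   target_gene = paste0("HUM_", rownames(m))))
  res <- convert_matrix(expression_matrix(m), tab)
  expect_equal(nrow(res$converted$counts), nrow(m))
  expect_equal(as.matrix(res$converted$counts)[paste0("HUM_", rownames(m)), ],
               m, ignore_attr = TRUE)
  expect_equal(res$report$pseudobulk_count_efficiency, 100)
  expect_equal(res$report$gene_mapping_rate, 100)
})

test_that("many-to-one sum adds the source rows", {
  x <- simple_matrix(matrix(c(2, 3), nrow = 2), c("A", "B"))
  tab <- ortholog_table(data.frame(source_gene = c("A", "B"),
                                   target_gene = c("H", "H")))
  res <- convert_matrix(x, tab, conversion_policy(many_to_one = "sum"))
  expect_equal(as.vector(res$converted$counts["H", ]), 5)
})

test_that("one-to-many expand replicates the source row into each target", {
  x <- simple_matrix(matrix(c(4, 1), nrow = 1), "A")
  tab <- ortholog_table(data.frame(source_gene = c("A", "A"),
                                   target_gene = c("H1", "H2")))
  res <- convert_matrix(x, tab, conversion_policy(one_to_many = "expand"))
  expect_true(any(grepl("exceeds 100", res$report$warnings)))
  expect_equal(as.matrix(res$converted$counts),
               matrix(c(4, 1, 4, 1), nrow = 2, byrow = TRUE,
                      dimnames = list(c("H1", "H2"), c("c1", "c2"))))
  expect_equal(sum(res$converted$counts), 2 * sum(x$counts))
})

test_that("max_total keeps the dominant source and breaks ties lexicographically", {
  x <- simple_matrix(matrix(c(5, 1, 9, 2), nrow = 2, byrow = TRUE),
                     c("B", "A"))
  tab <- ortholog_table(data.frame(source_gene = c("A", "B"),
                                   target_gene = c("H", "H")))
  res <- convert_matrix(x, tab, conversion_policy(many_to_one = "max_total"))
  expect_equal(as.vector(res$converted$counts["H", ]), c(9, 2)) # A wins on total
  # tie: equal totals -> lexicographically smallest source id
  x2 <- simple_matrix(matrix(c(5, 1, 4, 2), nrow = 2, byrow = TRUE),
                      c("B", "A"))
  res2 <- convert_matrix(x2, tab, conversion_policy(many_to_one = "max_total"))
  expect_equal(as.vector(res2$converted$counts["H", ]), c(4, 2))
})

test_that("drop_group removes shared targets and unmapped policy tags rows", {
  x <- simple_matrix(matrix(c(2, 3, 7), nrow = 3), c("A", "B", "Zz"))
  tab <- ortholog_table(data.frame(source_gene = c("A", "B"),
                                   target_gene = c("H", "H")))
  res <- suppressWarnings(convert_matrix(
    x, tab, conversion_policy(many_to_one = "drop_group",
                              unmapped = "retain_tagged")))
  expect_equal(rownames(res$converted$counts), "unmapped:Zz")
  expect_equal(as.vector(res$converted$counts["unmapped:Zz", ]), 7)
  expect_setequal(res$dropped_ambiguous, c("A", "B"))
  expect_setequal(res$unmapped_features, "Zz")
})

test_that("case-insensitive matching is opt-in", {
  x <- simple_matrix(matrix(c(2, 3), nrow = 2), c("TRP53", "Myc"))
  tab <- ortholog_table(data.frame(source_gene = c("Trp53", "Myc"),
                                   target_gene = c("TP53", "MYC")))
  res_strict <- convert_matrix(x, tab)
  expect_equal(rownames(res_strict$converted$counts), "MYC")
  res_fold <- convert_matrix(x, tab,
                             conversion_policy(case_insensitive = TRUE))
  expect_setequal(rownames(res_fold$converted$counts), c("TP53", "MYC"))
})

test_that("zero mappable features errors with mapping rate attached", {
  x <- simple_matrix(matrix(1:2, nrow = 2), c("A", "B"))
  tab <- ortholog_table(data.frame(source_gene = "Q", target_gene = "H"))
  err <- tryCatch(convert_matrix(x, tab), condition = function(c) c)
  expect_s3_class(err, "orthograft_no_features_mapped")
  expect_match(conditionMessage(err), "no features mapped")
  expect_equal(err$mapping_rate, 0)
})

test_that("sparse conversion equals the dense brute-force oracle", {
  withr::local_seed(22)
  policies <- all_policies()
  n_instances <- 200
  for (i in seq_len(n_instances)) {
    pol <- policies[(i - 1) %% nrow(policies) + 1, ]
    n_g <- sample(5:50, 1)
    n_o <- sample(2:20, 1)
    m <- rand_count_matrix(n_g, n_o)
    pairs <- rand_pair_table(rownames(m))
    x <- expression_matrix(m)
    tab <- ortholog_table(pairs)
    p <- conversion_policy(pol$many_to_one, pol$one_to_many, pol$unmapped)
    ref <- oracle_convert(m, pairs, pol$many_to_one, pol$one_to_many,
                          pol$unmapped)
    res <- tryCatch(
      suppressWarnings(convert_matrix(x, tab, p)),
      orthograft_no_features_mapped = function(e) e)
    if (inherits(res, "orthograft_no_features_mapped")) {
      expect_true(all(ref$fate == "dropped_unmapped"))
      next
    }
    expect_identical(rownames(res$converted$counts), rownames(ref$matrix))
    expect_equal(dense_of(res$converted), ref$matrix)
    expect_identical(res$plan$fate, unname(ref$fate))
    # observation passthrough
    expect_identical(obs_ids(res$converted), colnames(m))
  }
})

test_that("conservation holds exactly for policy (sum, drop, drop)", {
  withr::local_seed(23)
  for (i in 1:25) {
    m <- rand_count_matrix(sample(5:40, 1), sample(2:10, 1))
    pairs <- rand_pair_table(rownames(m))
    tab <- ortholog_table(pairs)
    p <- conversion_policy("sum", "drop", "drop")
    mapped <- pairs[!is.na(pairs$target_gene), ]
    n_targets <- vapply(rownames(m), function(g) {
      length(unique(mapped$target_gene[mapped$source_gene == g]))
    }, integer(1))
    keep <- names(n_targets)[n_targets == 1]
    expected <- sum(m[keep, , drop = FALSE])
    res <- tryCatch(suppressWarnings(convert_matrix(expression_matrix(m),
                                                    tab, p)),
                    orthograft_no_features_mapped = function(e) NULL)
    got <- if (is.null(res)) 0 else sum(res$converted$counts)
    expect_identical(got, expected)
  }
})

test_that("expansion inflation is bounded by the maximum fan-out", {
  withr::local_seed(24)
  for (i in 1:10) {
    m <- rand_count_matrix(20, 5)
    pairs <- rand_pair_table(rownames(m), p_unmapped = 0.1)
    tab <- ortholog_table(pairs)
    fmax <- max(lengths(forward_index(tab)))
    res <- suppressWarnings(convert_matrix(
      expression_matrix(m), tab,
      conversion_policy("sum", "expand", "drop")))
    expect_lte(sum(res$converted$counts), fmax * sum(m))
  }
})

test_that("conversion is equivariant under observation permutation", {
  withr::local_seed(25)
  m <- rand_count_matrix(20, 8)
  pairs <- rand_pair_table(rownames(m))
  tab <- ortholog_table(pairs)
  perm <- sample(ncol(m))
  res1 <- suppressWarnings(convert_matrix(expression_matrix(m), tab))
  res2 <- suppressWarnings(
    convert_matrix(expression_matrix(m[, perm]), tab))
  expect_equal(dense_of(res2$converted), dense_of(res1$converted)[, perm])
})

test_that("converting a converted matrix with the identity table is idempotent", {
  withr::local_seed(26)
  m <- rand_count_matrix(15, 5)
  tab <- ortholog_table(data.frame(source_gene = rownames(m),
                                   target_gene = toupper(rownames(m))))
  res <- convert_matrix(expression_matrix(m), tab)
  human_ids <- rownames(res$converted$counts)
  id_tab <- ortholog_table(data.frame(source_gene = human_ids,
                                      target_gene = human_ids))
  res2 <- convert_matrix(res$converted, id_tab)
  expect_equal(as.matrix(res2$converted$counts),
               as.matrix(res$converted$counts))
})

test_that("conversion_plan fates match realized fates, counts untouched", {
  withr::local_seed(27)
  for (i in 1:20) {
    m <- rand_count_matrix(sample(5:30, 1), sample(2:8, 1))
    pairs <- rand_pair_table(rownames(m))
    tab <- ortholog_table(pairs)
    pol <- all_policies()[sample(12, 1), ]
    p <- conversion_policy(pol$many_to_one, pol$one_to_many, pol$unmapped)
    x <- expression_matrix(m)
    plan <- conversion_plan(tab, x, p)
    res <- tryCatch(suppressWarnings(convert_matrix(x, tab, p)),
                    orthograft_no_features_mapped = function(e) NULL)
    if (is.null(res)) {
      expect_true(all(plan$fate == "dropped_unmapped"))
    } else {
      expect_identical(plan, res$plan)
    }
  }
  # explicit tiny cases
  tab <- ortholog_table(data.frame(source_gene = "A", target_gene = "H"))
  plan <- conversion_plan(tab, c("A", "Zz"))
  expect_equal(plan$fate, c("kept", "dropped_unmapped"))
  expect_equal(plan$targets[[1]], "H")

  tab2 <- ortholog_table(data.frame(source_gene = c("A", "B"),
                                    target_gene = c("H", "H")))
  plan2 <- conversion_plan(tab2, c("A", "B"),
                           conversion_policy(many_to_one = "drop_group"))
  expect_equal(plan2$fate, c("dropped_ambiguous", "dropped_ambiguous"))
})

test_that("metadata and embeddings pass through unchanged", {
  withr::local_seed(28)
  m <- rand_count_matrix(10, 4)
  om <- tibble::tibble(obs_id = colnames(m), cluster = c("a", "a", "b", "b"),
                       sx = 1:4, sy = 4:1)
  emb <- list(umap = matrix(rnorm(8), 4, 2))
  x <- expression_matrix(m, obs_meta = om, embeddings = emb)
  tab <- ortholog_table(data.frame(source_gene = rownames(m),
                                   target_gene = toupper(rownames(m))))
  res <- convert_matrix(x, tab)
  expect_identical(res$converted$obs_meta, x$obs_meta)
  expect_equal(res$converted$embeddings$umap, x$embeddings$umap,
               ignore_attr = TRUE)
})
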