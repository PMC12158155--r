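#' Simulation designs
#'
#' `simulation_design()` parameterizes a grouped negative-binomial count
#' simulator emulating droplet scRNA-seq: gene base means are log-normal,
#' a `de_fraction` of genes receive group-specific multiplicative
#' log2-fold-changes of scale `lfc_scale`, per-cell size factors are
#' uniform on `depth_range`, and counts are NB with variance
#' `mu + mu^2 / nb_dispersion`.
#'
#' `table_design()` parameterizes a synthetic ortholog table over a given
#' feature universe: designed numbers of one2one pairs, one2many sources
#' (fan-out uniform in `[2, max_fanout]`), complete-bipartite many2many
#' blocks of `block_size` x `block_size`, and unmapped sources. Target
#' symbols are uppercase transforms of the source with collision-free
#' suffixes.
#'
#' @param n_genes,n_cells,n_groups Matrix dimensions and number of
#'   ground-truth cell groups.
#' @param de_fraction Fraction of genes differentially expressed between
#'   groups, in `[0, 1]`.
#' @param lfc_scale Standard deviation of the log2 fold changes assigned
#'   to differentially expressed genes.
#' @param nb_dispersion NB dispersion `theta` (variance `mu + mu^2/theta`).
#' @param depth_range Length-2 numeric, bounds of per-cell size factors.
#' @param seed Integer seed; part of the design so all outputs are
#'   reproducible.
#' @return A `simulation_design` / `table_design` list.
#' @export
simulation_design <- function(n_genes = 400, n_cells = 150, n_groups = 3,
                              de_fraction = 0.2, lfc_scale = 1.5,
                              nb_dispersion = 2,
                              depth_range = c(0.6, 1.6), seed = 1) {
  stopifnot(n_genes > 0, n_cells > 0, n_groups > 0,
            de_fraction >= 0, de_fraction <= 1,
            lfc_scale >= 0, nb_dispersion > 0,
            length(depth_range) == 2L, all(depth_range > 0),
            depth_range[1] <= depth_range[2])
  structure(as.list(environment()), class = "simulation_design")
}

#' @rdname simulation_design
#' @param n_one2one,n_one2many,n_many2many_blocks,n_unmapped Designed
#'   counts of each mapping class.
#' @param max_fanout Maximum one2many fan-out (`>= 2`).
#' @param block_size Sources (and targets) per many2many block (`>= 2`).
#' @param case_style `"mouse_title_case"` generates Title-case source
#'   symbols; `"shared_upper"` leaves sources uppercase.
#' @export
table_design <- function(n_one2one = 50, n_one2many = 10, max_fanout = 3,
                         n_many2many_blocks = 5, block_size = 2,
                         n_unmapped = 15,
                         case_style = c("mouse_title_case", "shared_upper"),
                         seed = 1) {
  case_style <- match.arg(case_style)
  stopifnot(n_one2one >= 0, n_one2many >= 0, n_many2many_blocks >= 0,
            n_unmapped >= 0, block_size >= 2,
            n_one2many == 0 || max_fanout >= 2)
  structure(as.list(environment()), class = "table_design")
}

# number of source features a table design consumes
.table_design_size <- function(design) {
  design$n_one2one + design$n_one2many +
    design$n_many2many_blocks * design$block_size + design$n_unmapped
}

#' Simulate a grouped negative-binomial count matrix
#'
#' Counts follow `NB(mean = base_g * fc[g, group(c)] * size_c,
#' variance = mean + mean^2 / nb_dispersion)` with log-normal gene base
#' means. Ground-truth group labels are stored in `obs_meta$group`.
#' Deterministic given `design$seed`.
#'
#' @param design A [simulation_design()].
#' @param gene_prefix Prefix for generated gene symbols (Title-case,
#'   mouse-style by default).
#' @param obs_prefix Prefix for observation ids.
#' @return An [expression_matrix()] with ground-truth labels in
#'   `obs_meta$group`; the per-gene/group mean parameters are attached as
#'   attribute `"true_means"` for generator-level checks.
#' @export
simulate_counts <- function(design, gene_prefix = "Simgene",
                            obs_prefix = "cell") {
  stopifnot(inherits(design, "simulation_design"))
  if (design$n_cells < design$n_groups) {
    abort("n_cells must be at least n_groups")
  }
  withr::with_seed(design$seed, {
    g <- design$n_genes; n <- design$n_cells; k <- design$n_groups
    genes <- sprintf("%s%04d", gene_prefix, seq_len(g))
    cells <- sprintf("%s_%04d", obs_prefix, seq_len(n))
    group <- rep_len(seq_len(k), n)

    base <- rlnorm(g, meanlog = 1, sdlog = 1)
    n_de <- round(design$de_fraction * g)
    de_genes <- if (n_de > 0) sample.int(g, n_de) else integer(0)
    lfc <- matrix(0, nrow = g, ncol = k)
    if (length(de_genes) > 0 && k > 1) {
      # each DE gene gets a group-specific log2 fold change
      for (j in seq_len(k)) {
        lfc[de_genes, j] <- rnorm(length(de_genes), 0, design$lfc_scale)
      }
    }
    fc <- 2^lfc
    size_c <- runif(n, design$depth_range[1], design$depth_range[2])

    mu <- base * fc[, group, drop = FALSE] *
      matrix(size_c, nrow = g, ncol = n, byrow = TRUE)
    counts <- matrix(
      rnbinom(g * n, size = design$nb_dispersion, mu = as.vector(mu)),
      nrow = g, dimnames = list(genes, cells))

    x <- expression_matrix(
      counts,
      obs_meta = tibble(obs_id = cells, group = as.character(group))
    )
    attr(x, "true_means") <- list(base = base, fc = fc, size = size_c,
                                  de_genes = genes[de_genes],
                                  seed = design$seed)
    x
  })
}

#' Simulate an ortholog table with known ground truth
#'
#' Consumes features from `feature_ids` in order and assigns them the
#' designed mapping classes. Deterministic given `design$seed`.
#'
#' @param design A [table_design()].
#' @param feature_ids Source feature universe; must contain at least the
#'   number of genes the design consumes.
#' @return A list with `table` (an [ortholog_table()]) and `truth`
#'   (tibble: `feature_id`, designed `class`).
#' @export
simulate_ortholog_table <- function(design, feature_ids) {
  stopifnot(inherits(design, "table_design"))
  need <- .table_design_size(design)
  if (length(feature_ids) < need) {
    abort(sprintf("design consumes %d features but only %d supplied",
                  need, length(feature_ids)))
  }
  withr::with_seed(design$seed, {
    restyle <- function(ids) {
      if (design$case_style == "mouse_title_case") {
        paste0(toupper(substr(ids, 1, 1)), tolower(substr(ids, 2, nchar(ids))))
      } else {
        toupper(ids)
      }
    }
    pool <- feature_ids[seq_len(need)]
    idx <- 0L
    take <- function(n) {
      out <- pool[idx + seq_len(n)]
      idx <<- idx + n
      out
    }
    rows <- list(); truth <- list()

    s <- take(design$n_one2one)
    if (length(s) > 0) {
      rows[[length(rows) + 1L]] <-
        tibble(source_gene = restyle(s), target_gene = toupper(s))
      truth[[length(truth) + 1L]] <-
        tibble(feature_id = restyle(s), class = "one2one")
    }

    s <- take(design$n_one2many)
    if (length(s) > 0) {
      fan <- sample(2:design$max_fanout, length(s), replace = TRUE)
      rows[[length(rows) + 1L]] <- tibble(
        source_gene = rep(restyle(s), fan),
        target_gene = unlist(lapply(seq_along(s), function(i) {
          paste0(toupper(s[i]), "-H", seq_len(fan[i]))
        }))
      )
      truth[[length(truth) + 1L]] <-
        tibble(feature_id = restyle(s), class = "one2many")
    }

    if (design$n_many2many_blocks > 0) {
      for (b in seq_len(design$n_many2many_blocks)) {
        s <- take(design$block_size)
        tgts <- paste0(toupper(s[1]), "-M", seq_len(design$block_size))
        rows[[length(rows) + 1L]] <- tibble(
          source_gene = rep(restyle(s), each = design$block_size),
          target_gene = rep(tgts, times = design$block_size)
        )
        truth[[length(truth) + 1L]] <-
          tibble(feature_id = restyle(s), class = "many2many")
      }
    }

    s <- take(design$n_unmapped)
    if (length(s) > 0) {
      rows[[length(rows) + 1L]] <-
        tibble(source_gene = restyle(s), target_gene = NA_character_)
      truth[[length(truth) + 1L]] <-
        tibble(feature_id = restyle(s), class = "unmapped")
    }

    pairs <- dplyr::bind_rows(rows)
    pairs$source_biotype <- NA_character_
    list(
      table = ortholog_table(pairs, source_species = "synthetic"),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Simulate a dual-species (PDX-like) mixed matrix
#'
#' Stacks a human-namespace gene block and a mouse-namespace gene block
#' over the same observations, emulating the mixed count matrix of a
#' patient-derived xenograft. Human genes get uppercase symbols; mouse
#' genes Title-case symbols with an ortholog table generated from
#' `table_design`. With `prefix_mode = TRUE`, features are prefixed
#' `"GRCh38_"` / `"mm10_"` as in multi-genome CellRanger output.
#'
#' @param human_design,mouse_design [simulation_design()]s sharing
#'   `n_cells`.
#' @param tbl_design A [table_design()] over the mouse genes.
#' @param prefix_mode Prefix features by genome build.
#' @return List with `x` (stacked [expression_matrix()]), `truth` (tibble
#'   `feature_id`, `species`), `table` (the mouse->human
#'   [ortholog_table()]), and `human`/`mouse` block matrices.
#' @export
simulate_pdx <- function(human_design, mouse_design,
                         tbl_design = table_design(), prefix_mode = TRUE) {
  stopifnot(inherits(human_design, "simulation_design"),
            inherits(mouse_design, "simulation_design"))
  if (human_design$n_cells != mouse_design$n_cells) {
    abort("human and mouse designs must share n_cells")
  }
  hx <- simulate_counts(human_design, gene_prefix = "Hsgene")
  rownames(hx$counts) <- toupper(rownames(hx$counts))
  hx$feature_meta <- NULL
  mx <- simulate_counts(mouse_design, gene_prefix = "Mmgene")

  need <- .table_design_size(tbl_design)
  if (mouse_design$n_genes < need) {
    abort("mouse design has fewer genes than the table design consumes")
  }
  sim_tab <- simulate_ortholog_table(tbl_design, feature_ids(mx))
  # the table restyles mouse symbols; rename matrix rows to match
  restyled <- sim_tab$truth$feature_id
  rownames(mx$counts)[seq_len(need)] <- restyled

  h_ids <- rownames(hx$counts)
  m_ids <- rownames(mx$counts)
  if (prefix_mode) {
    h_ids_out <- paste0("GRCh38_", h_ids)
    m_ids_out <- paste0("mm10_", m_ids)
  } else {
    h_ids_out <- h_ids
    m_ids_out <- m_ids
  }
  hm <- hx$counts; rownames(hm) <- h_ids_out
  mm <- mx$counts; rownames(mm) <- m_ids_out
  stacked <- rbind(hm, mm)
  x <- expression_matrix(stacked, obs_meta = hx$obs_meta)
  truth <- tibble(
    feature_id = c(h_ids_out, m_ids_out),
    species = c(rep("human", length(h_ids_out)),
                rep("nonhuman", length(m_ids_out)))
  )
  list(x = x, truth = truth, table = sim_tab$table,
       human = expression_matrix(hm, obs_meta = hx$obs_meta),
       mouse = expression_matrix(mm, obs_meta = mx$obs_meta))
}
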