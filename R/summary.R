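# Compartment accounting (Venn bookkeeping) and per-functional-group N:C
# density summaries.

#' Venn counts of compartment detection
#'
#' Counts proteins detected only in the nucleus, only in the cytosol, and in
#' both, from the `status` column of a partition-record set. The union
#' identity `total = |N| + |C| - |N & C|` holds by construction.
#'
#' @param records a partition-record tibble (unique `protein_id` per row).
#' @return a named list: `nuc_only`, `cyt_only`, `both`, `total`.
#' @export
venn_counts <- function(records) {
  if (anyDuplicated(records$protein_id)) {
    abort_arg("records must be deduplicated by protein_id")
  }
  nuc_only <- sum(records$status == "nuc_only")
  cyt_only <- sum(records$status == "cyt_only")
  both <- sum(records$status == "both")
  list(nuc_only = nuc_only, cyt_only = cyt_only, both = both,
       total = nuc_only + cyt_only + both)
}

#' Per-group N:C density curves
#'
#' Gaussian-kernel density of log10 N:C ratios for each functional group,
#' evaluated on one common grid. Each group's curve is rescaled by its share
#' of proteins (`n_group / n_total`), so a subgroup's curve never exceeds the
#' all-protein curve and curve masses are comparable across panels. Proteins
#' without a finite ratio (detected in one compartment) are excluded from
#' the kernel and reported as end-of-axis counts.
#'
#' @param records a partition-record tibble with `log10_nc` and `status`.
#' @param groups a data frame `protein_id`, `group` (repeated rows allowed
#'   for multi-membership); `NULL` gives a single group `"all"`.
#' @param bandwidth kernel bandwidth; default Silverman's rule per group.
#' @param grid_n number of grid points.
#' @param grid_range range of the log10 N:C grid; defaults to the span of
#'   the finite ratios.
#' @return a list: `curves` — tibble `group`, `grid`, `density`,
#'   `n_proteins`; `censored` — tibble `group`, `nuc_only`, `cyt_only`.
#' @export
group_densities <- function(records, groups = NULL, bandwidth = NULL,
                            grid_n = 512L, grid_range = NULL) {
  if (is.null(groups)) {
    groups <- tibble(protein_id = records$protein_id, group = "all")
  }
  groups <- as_tibble(groups)
  finite <- dplyr::filter(records, is.finite(.data$log10_nc))
  n_total <- nrow(finite)
  per_group <- split(groups$protein_id, groups$group)
  vals_list <- lapply(per_group, function(ids) {
    finite$log10_nc[finite$protein_id %in% ids]
  })
  bw_list <- lapply(vals_list, function(v) {
    if (length(v) >= 2L && stats::sd(v) > 0) bandwidth %||% stats::bw.nrd0(v)
    else bandwidth %||% 0.1
  })
  if (is.null(grid_range)) {
    # pad past the data range so kernel tails carry negligible mass outside
    pad <- 5 * max(unlist(bw_list), 0.1)
    grid_range <- if (n_total) range(finite$log10_nc) + c(-pad, pad)
                  else c(-1, 1)
  }
  grid <- seq(grid_range[1], grid_range[2], length.out = grid_n)

  curves <- lapply(names(per_group), function(g) {
    vals <- vals_list[[g]]
    n <- length(vals)
    if (n == 0L) {
      return(tibble(group = g, grid = grid, density = rep(0, grid_n),
                    n_proteins = 0L))
    }
    dens <- if (n == 1L) {
      # degenerate group: a single kernel at the observation
      stats::dnorm(grid, mean = vals, sd = bw_list[[g]])
    } else {
      d <- stats::density(vals, bw = bw_list[[g]], from = grid_range[1],
                          to = grid_range[2], n = grid_n)
      d$y
    }
    tibble(group = g, grid = grid, density = dens * n / n_total,
           n_proteins = n)
  })
  censored <- lapply(names(per_group), function(g) {
    sub <- dplyr::filter(records, .data$protein_id %in% per_group[[g]])
    tibble(group = g,
           nuc_only = sum(sub$status == "nuc_only"),
           cyt_only = sum(sub$status == "cyt_only"))
  })
  list(curves = dplyr::bind_rows(curves),
       censored = dplyr::bind_rows(censored))
}
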