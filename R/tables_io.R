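# Readers and writers for every tabular artifact: protein-groups-style
# intensity tables (MaxQuant-compatible column aliases), spike amounts,
# id lists, machinery and functional-group assignments, and the reports.
#
# Dialect: tab-separated, UTF-8, "NA" for missing. Zero intensities are
# treated as missing on read.

# canonical metadata columns and their MaxQuant-style aliases
.meta_aliases <- list(
  min_pep = c("min_pep", "PEP"),
  unique_peptides = c("unique_peptides", "Unique peptides"),
  only_by_site = c("only_by_site", "Only identified by site")
)

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Validate an intensity table
#'
#' Checks the long-form `IntensityTable` contract: one row per
#' (protein, sample); non-negative intensities where present; a single role
#' and replicate per sample; roles drawn from the known set.
#'
#' @param table a tibble with columns `protein_id`, `sample_id`, `role`,
#'   `replicate`, `intensity`, `min_pep`, `unique_peptides`, `only_by_site`.
#' @return the table, invisibly; errors describe the violated invariant.
#' @export
validate_intensity_table <- function(table) {
  need <- c("protein_id", "sample_id", "role", "replicate", "intensity",
            "min_pep", "unique_peptides", "only_by_site")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    abort_arg(sprintf("intensity table lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(table[c("protein_id", "sample_id")])) {
    abort_arg("duplicate (protein_id, sample_id) rows")
  }
  if (any(table$intensity < 0, na.rm = TRUE)) {
    abort_arg("negative intensities present")
  }
  bad_role <- setdiff(unique(table$role), sample_roles())
  if (length(bad_role)) {
    abort_arg(sprintf("unknown sample role(s): %s",
                      paste(bad_role, collapse = ", ")))
  }
  per_sample <- dplyr::distinct(table, .data$sample_id, .data$role,
                                .data$replicate)
  if (anyDuplicated(per_sample$sample_id)) {
    abort_arg("a sample_id carries more than one (role, replicate)")
  }
  invisible(table)
}

#' Read a wide intensity table
#'
#' Reads a protein-groups-style TSV (one row per protein or proteoform, one
#' intensity column per sample) into the long-form `IntensityTable` used by
#' the pipeline. The sample manifest assigns a role and replicate to every
#' intensity column; metadata columns are picked up under their canonical
#' names or their MaxQuant aliases (`PEP`, `Unique peptides`,
#' `Only identified by site`). Zero intensities become missing.
#'
#' @param path TSV file with a `protein_id` column (alias `Protein IDs`),
#'   metadata columns and one column per sample (e.g. `iBAQ nuc_1`).
#' @param sample_manifest a data frame with columns `column`, `sample_id`,
#'   `role`, `replicate` covering every intensity column.
#' @return a validated long-form tibble.
#' @export
read_intensity_table <- function(path, sample_manifest) {
  if (!file.exists(path)) abort_arg(sprintf("file not found: %s", path))
  need <- c("column", "sample_id", "role", "replicate")
  if (!all(need %in% names(sample_manifest))) {
    abort_arg("sample_manifest needs columns: column, sample_id, role, replicate")
  }
  wide <- read_tsv_quiet(path)
  id_col <- intersect(c("protein_id", "Protein IDs"), names(wide))[1]
  if (is.na(id_col)) abort_arg("no protein id column (protein_id / Protein IDs)")
  absent <- setdiff(sample_manifest$column, names(wide))
  if (length(absent)) {
    abort_arg(sprintf("manifest column(s) absent from file: %s",
                      paste(absent, collapse = ", ")))
  }
  meta <- lapply(.meta_aliases, function(alias) {
    hit <- intersect(alias, names(wide))
    if (length(hit)) wide[[hit[1]]] else NULL
  })
  base <- tibble(
    protein_id = as.character(wide[[id_col]]),
    min_pep = as.numeric(meta$min_pep %||% rep(0, nrow(wide))),
    unique_peptides = as.integer(meta$unique_peptides %||% rep(2L, nrow(wide))),
    only_by_site = as.logical(meta$only_by_site %||% rep(FALSE, nrow(wide)))
  )
  long <- lapply(seq_len(nrow(sample_manifest)), function(i) {
    m <- sample_manifest[i, ]
    intensity <- as.numeric(wide[[m$column]])
    intensity[!is.na(intensity) & intensity == 0] <- NA_real_
    dplyr::bind_cols(
      tibble(protein_id = base$protein_id,
             sample_id = as.character(m$sample_id),
             role = as.character(m$role),
             replicate = as.integer(m$replicate),
             intensity = intensity),
      base[c("min_pep", "unique_peptides", "only_by_site")]
    )
  })
  out <- dplyr::bind_rows(long)
  if (anyDuplicated(out[c("protein_id", "sample_id")])) {
    abort_arg("duplicate (protein_id, sample_id) in file")
  }
  validate_intensity_table(out)
  out
}

#' Write an intensity table (wide) and its sample manifest
#'
#' Inverse of [read_intensity_table()]: pivots the long table to one `iBAQ
#' <sample_id>` column per sample and writes the manifest alongside
#' (`<path>.manifest.tsv`).
#'
#' @param table a long-form intensity table.
#' @param path output TSV path.
#' @return the manifest tibble, invisibly.
#' @export
write_intensity_table <- function(table, path) {
  validate_intensity_table(table)
  manifest <- dplyr::distinct(table, .data$sample_id, .data$role,
                              .data$replicate)
  manifest <- dplyr::mutate(manifest,
                            column = paste("iBAQ", .data$sample_id),
                            .before = 1L)
  meta <- dplyr::summarise(
    dplyr::group_by(table, .data$protein_id),
    min_pep = min(.data$min_pep),
    unique_peptides = max(.data$unique_peptides),
    only_by_site = any(.data$only_by_site),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    dplyr::transmute(table, .data$protein_id,
                     column = paste("iBAQ", .data$sample_id),
                     .data$intensity),
    names_from = "column", values_from = "intensity"
  )
  readr::write_tsv(dplyr::left_join(meta, wide, by = "protein_id"), path)
  readr::write_tsv(manifest, paste0(path, ".manifest.tsv"))
  invisible(manifest)
}

#' Read an identifier list
#'
#' One identifier per line; duplicates are dropped. Used for contaminant
#' flags, keep lists and similar sets.
#'
#' @param path list file.
#' @return a character vector (a set).
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) abort_arg(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty identifier list: ", path, call. = FALSE)
    return(character())
  }
  bad <- grepl("\t", lines, fixed = TRUE)
  if (any(bad)) {
    abort_arg(sprintf("malformed row at line %d of %s (embedded tab)",
                      which(bad)[1], path))
  }
  unique(lines)
}

#' Read a spike-in amount table
#'
#' Two tab-separated columns: `standard_id`, `amount_fmol`.
#'
#' @param path TSV file.
#' @return a `SpikeTable` tibble (`standard_id`, `known_amount`).
#' @export
read_spike_table <- function(path) {
  tab <- read_tsv_quiet(path, col_types = readr::cols(
    standard_id = readr::col_character(),
    amount_fmol = readr::col_double()
  ))
  if (any(!is.finite(tab$amount_fmol)) || any(tab$amount_fmol <= 0)) {
    bad <- which(!is.finite(tab$amount_fmol) | tab$amount_fmol <= 0)[1]
    abort_arg(sprintf("non-positive spike amount at line %d of %s",
                      bad + 1L, path))
  }
  tibble(standard_id = tab$standard_id, known_amount = tab$amount_fmol)
}

#' Read a transport-machinery list
#'
#' One `id<TAB>class` per line; classes name the machinery categories
#' assigned regardless of scores (NUPs, NTRs, NPC, CRM1_cofactor).
#'
#' @param path TSV file with columns `protein_id`, `class` (no header
#'   required: two unnamed columns are accepted).
#' @return a named character vector: names are protein ids, values classes.
#' @export
read_machinery_list <- function(path) {
  if (!file.exists(path)) abort_arg(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, header = FALSE, col.names = c("protein_id", "class"),
                           colClasses = "character")
  if (nrow(tab) && identical(tolower(tab$protein_id[1]), "protein_id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  stats::setNames(tab$class, tab$protein_id)
}

#' Read functional-group assignments
#'
#' One `protein_id<TAB>group` per line; repeated rows express
#' multi-membership.
#'
#' @param path TSV file.
#' @return a tibble with columns `protein_id`, `group`.
#' @export
read_group_assignments <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("protein_id", "group"),
                           colClasses = "character")
  if (nrow(tab) && identical(tolower(tab$protein_id[1]), "protein_id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (any(!nzchar(tab$group))) abort_arg("empty group label in assignments")
  dplyr::distinct(as_tibble(tab))
}

#' Write and re-read pipeline reports
#'
#' Writes the partition and cargo reports as TSV with a deterministic column
#' order; ratios are carried on the log10 scale alongside the linear value,
#' and censored partition records appear with status `nuc_only` / `cyt_only`.
#' Round-tripping a report through its reader returns identical values.
#'
#' @param partition a partition-record tibble (see [compute_partition()]);
#'   `NULL` to skip.
#' @param cargo a cargo-score tibble (see [classify_experiment()]); `NULL`
#'   to skip.
#' @param dir output directory, created if needed.
#' @return named character vector of the files written.
#' @export
write_reports <- function(partition = NULL, cargo = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (!is.null(partition)) {
    cols <- c("protein_id", "conc_nuc", "conc_cyt", "nc_ratio", "log10_nc",
              "status", "flagged", "kept_override")
    path <- file.path(dir, "partition_report.tsv")
    readr::write_tsv(partition[cols], path)
    written["partition"] <- path
  }
  if (!is.null(cargo)) {
    cols <- c("protein_id", "molar_fraction_bound", "molar_fraction_input",
              "input_enrichment", "ran_stimulation",
              "enrichment_is_bound_estimate", "stimulation_is_bound_estimate",
              "detected_in", "category")
    path <- file.path(dir, "cargo_report.tsv")
    readr::write_tsv(cargo[cols], path)
    written["cargo"] <- path
  }
  written
}

#' @rdname write_reports
#' @param path report file path.
#' @export
read_partition_report <- function(path) {
  read_tsv_quiet(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    status = readr::col_character(),
    flagged = readr::col_logical(),
    kept_override = readr::col_logical(),
    .default = readr::col_double()
  ))
}

#' @rdname write_reports
#' @export
read_cargo_report <- function(path) {
  read_tsv_quiet(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    detected_in = readr::col_character(),
    category = readr::col_character(),
    enrichment_is_bound_estimate = readr::col_logical(),
    stimulation_is_bound_estimate = readr::col_logical(),
    .default = readr::col_double()
  ))
}

#' Write a truth table as a companion TSV
#'
#' Ground-truth columns are written with a `truth_` prefix so simulated
#' inputs and their truth can live side by side.
#'
#' @param truth a `TruthTable` tibble.
#' @param path output TSV path.
#' @export
write_truth_table <- function(truth, path) {
  out <- truth
  names(out)[-1] <- paste0("truth_", names(out)[-1])
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  tab <- read_tsv_quiet(path)
  names(tab) <- sub("^truth_", "", names(tab))
  as_tibble(tab)
}
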