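# Domain containers and TSV readers/writers shared by all pipeline stages.

#' Construct an abundance table
#'
#' A taxon-by-sample matrix of sequencing counts or relative abundances
#' together with its taxonomy annotation. This is the substrate of every
#' downstream stage (community typing, diversity, RAD statistics).
#'
#' @param values numeric matrix, taxa in rows (rownames = taxon ids),
#'   samples in columns (colnames = sample ids). Nonnegative.
#' @param mode `"counts"` (nonnegative integers, positive column sums) or
#'   `"relative"` (columns sum to 1 within 1e-9).
#' @param taxonomy data frame with columns `taxon_id`, `genus`,
#'   `subgenus_group` (NA except for Lactobacillus taxa). Taxa of the matrix
#'   absent from the annotation are recorded as genus `"unclassified"`.
#' @param level aggregation level of the rows: `"asv"`, `"subgenus_group"`
#'   or `"genus"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, mode = c("counts", "relative"),
                            taxonomy = NULL,
                            level = c("asv", "subgenus_group", "genus")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    vd_stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    vd_stop("'values' must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    vd_stop(sprintf("duplicate taxon id: %s",
                    rownames(values)[duplicated(rownames(values))][1]),
            "vagidyn_format_error")
  if (anyDuplicated(colnames(values)))
    vd_stop("duplicate sample id", "vagidyn_format_error")
  if (any(!is.finite(values)) || any(values < 0))
    vd_stop("abundance values must be finite and nonnegative",
            "vagidyn_parse_error")
  if (mode == "counts") {
    if (any(abs(values - round(values)) > 1e-9))
      vd_stop("counts-mode entries must be integers", "vagidyn_parse_error")
    cs <- colSums(values)
    if (any(cs <= 0))
      vd_stop(sprintf("sample '%s' has zero total count",
                      colnames(values)[which(cs <= 0)[1]]),
              "vagidyn_validation_error")
  } else {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9))
      vd_stop(sprintf("relative-mode column '%s' does not sum to 1",
                      colnames(values)[which(abs(cs - 1) > 1e-9)[1]]),
              "vagidyn_validation_error")
  }
  taxonomy <- complete_taxonomy(taxonomy, rownames(values), level)
  structure(list(values = values, mode = mode, taxonomy = taxonomy,
                 level = level),
            class = "abundance_table")
}

# Fill in genus="unclassified" for unannotated taxa; validate the
# Lactobacillus <-> subgenus_group correspondence.
complete_taxonomy <- function(taxonomy, taxon_ids, level = "asv") {
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(taxon_id = character(), genus = character(),
                           subgenus_group = character(),
                           stringsAsFactors = FALSE)
  }
  need <- c("taxon_id", "genus", "subgenus_group")
  if (!all(need %in% names(taxonomy)))
    vd_stop("taxonomy must have columns taxon_id, genus, subgenus_group",
            "vagidyn_format_error")
  taxonomy <- taxonomy[, need]
  taxonomy$subgenus_group[!is.na(taxonomy$subgenus_group) &
                            taxonomy$subgenus_group == ""] <- NA_character_
  if (anyDuplicated(taxonomy$taxon_id))
    vd_stop("duplicate taxon_id in taxonomy", "vagidyn_format_error")
  lacto <- !is.na(taxonomy$genus) & taxonomy$genus == "Lactobacillus"
  # at genus aggregation the row "Lactobacillus" legitimately has no group
  if (level == "asv" && any(lacto & is.na(taxonomy$subgenus_group)))
    vd_stop("Lactobacillus taxa must carry a subgenus_group",
            "vagidyn_validation_error")
  if (any(!lacto & !is.na(taxonomy$subgenus_group)))
    vd_stop("subgenus_group is only allowed for genus Lactobacillus",
            "vagidyn_validation_error")
  missing <- setdiff(taxon_ids, taxonomy$taxon_id)
  if (length(missing)) {
    taxonomy <- rbind(taxonomy,
                      data.frame(taxon_id = missing, genus = "unclassified",
                                 subgenus_group = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  rownames(taxonomy) <- NULL
  taxonomy[match(taxon_ids, taxonomy$taxon_id), , drop = FALSE]
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d taxa x %d samples (%s mode, %s level)\n",
              nrow(x$values), ncol(x$values), x$mode, x$level))
  invisible(x)
}

#' Read a taxon-by-sample count table
#'
#' Reads a tab-delimited table whose first column is `taxon_id` and whose
#' remaining columns are samples. An optional leading comment line
#' `#mode=relative` declares a pre-normalized table; the default is counts.
#'
#' @param path path to the counts TSV.
#' @param taxonomy_path optional path to a taxonomy TSV with columns
#'   `asv_id`, `genus`, `subgenus_group` (empty allowed).
#' @return An [abundance_table()].
#' @export
read_count_table <- function(path, taxonomy_path = NULL) {
  lines <- readLines(path)
  mode <- "counts"
  hdr <- grep("^#", lines)
  if (length(hdr)) {
    m <- regmatches(lines[hdr], regexec("^#mode=(\\w+)", lines[hdr]))
    modes <- vapply(m, function(z) if (length(z)) z[2] else NA_character_, "")
    modes <- modes[!is.na(modes)]
    if (length(modes)) {
      if (!modes[1] %in% c("counts", "relative"))
        vd_stop(sprintf("unknown #mode= value '%s'", modes[1]),
                "vagidyn_parse_error")
      mode <- modes[1]
    }
    lines <- lines[-hdr]
  }
  df <- utils::read.delim(text = lines, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) vd_stop("counts table needs >= 1 sample column",
                            "vagidyn_format_error")
  taxa <- df[[1]]
  if (anyDuplicated(taxa))
    vd_stop(sprintf("duplicate taxon id '%s'", taxa[duplicated(taxa)][1]),
            "vagidyn_format_error")
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(taxa, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    vd_stop(sprintf("non-numeric entry '%s' at taxon '%s', sample '%s'",
                    vals[bad[1, 1], bad[1, 2]], taxa[bad[1, 1]],
                    colnames(vals)[bad[1, 2]]),
            "vagidyn_parse_error")
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg))
    vd_stop(sprintf("negative entry at taxon '%s', sample '%s'",
                    taxa[neg[1, 1]], colnames(num)[neg[1, 2]]),
            "vagidyn_parse_error")
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)
  abundance_table(num, mode = mode, taxonomy = taxonomy)
}

#' Read a taxonomy annotation table
#'
#' @param path TSV with columns `asv_id`, `genus`, `subgenus_group`.
#' @return Data frame with columns `taxon_id`, `genus`, `subgenus_group`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("asv_id", "genus") %in% names(df)))
    vd_stop("taxonomy must have columns asv_id and genus",
            "vagidyn_format_error")
  if (is.null(df$subgenus_group)) df$subgenus_group <- NA_character_
  data.frame(taxon_id = df$asv_id, genus = df$genus,
             subgenus_group = ifelse(df$subgenus_group == "" |
                                       is.na(df$subgenus_group),
                                     NA_character_, df$subgenus_group),
             stringsAsFactors = FALSE)
}

#' Write an abundance table to TSV
#'
#' Relative-mode tables get a `#mode=relative` header line so that
#' [read_count_table()] round-trips them.
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (table$mode == "relative") writeLines("#mode=relative", con)
  df <- data.frame(taxon_id = rownames(table$values),
                   table$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total. All community typing, diversity
#' and RAD computations operate on the resulting relative table.
#'
#' @param table a counts-mode [abundance_table()].
#' @return The table in relative mode; taxon order preserved.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode == "relative")
    vd_stop("table already relative", "vagidyn_usage_error")
  cs <- colSums(table$values)
  if (any(cs <= 0))
    vd_stop(sprintf("sample '%s' has zero total count",
                    colnames(table$values)[which(cs <= 0)[1]]),
            "vagidyn_validation_error")
  abundance_table(sweep(table$values, 2, cs, "/"), mode = "relative",
                  taxonomy = table$taxonomy, level = table$level)
}

#' Aggregate taxa to subgenus-group or genus level
#'
#' Lactobacillus ASVs aggregate to their subgenus group
#' (`L_crispatus_group`, `L_iners_group`, ...) at `subgenus_group` level and
#' to `"Lactobacillus"` at `genus` level; all other taxa aggregate to their
#' genus at both levels. Column totals are preserved exactly.
#'
#' @param table an [abundance_table()] at ASV level.
#' @param level `"subgenus_group"` or `"genus"`.
#' @return Aggregated [abundance_table()] in the same mode.
#' @export
aggregate_taxa <- function(table, level = c("subgenus_group", "genus")) {
  stopifnot(inherits(table, "abundance_table"))
  level <- match.arg(level)
  tx <- table$taxonomy
  lacto <- !is.na(tx$genus) & tx$genus == "Lactobacillus"
  label <- tx$genus
  if (level == "subgenus_group") label[lacto] <- tx$subgenus_group[lacto]
  agg <- rowsum(table$values, group = label, reorder = TRUE)
  if (max(abs(colSums(agg) - colSums(table$values))) > 1e-9)
    vd_stop("internal error: aggregation changed sample totals")
  new_tx <- data.frame(
    taxon_id = rownames(agg),
    genus = ifelse(rownames(agg) %in% LACTO_GROUPS, "Lactobacillus",
                   rownames(agg)),
    subgenus_group = ifelse(rownames(agg) %in% LACTO_GROUPS, rownames(agg),
                            NA_character_),
    stringsAsFactors = FALSE)
  abundance_table(agg, mode = table$mode, taxonomy = new_tx, level = level)
}

#' Construct a study design
#'
#' Maps each sample to its participant, treatment arm and time point, and
#' validates the longitudinal pairing structure: at most one sample per
#' participant per time point, and one arm per participant.
#'
#' @param df data frame with columns `sample_id`, `participant_id`, `arm`
#'   (`"placebo"`/`"treatment"`), `timepoint` (V1, D7, D14, D21, V2, V3) and
#'   optionally `day`.
#' @return A `study_design` data frame ordered by (participant, time point),
#'   with `timepoint` an ordered factor.
#' @export
study_design <- function(df) {
  need <- c("sample_id", "participant_id", "arm", "timepoint")
  if (!all(need %in% names(df)))
    vd_stop("metadata must have columns sample_id, participant_id, arm, timepoint",
            "vagidyn_format_error")
  if (anyDuplicated(df$sample_id))
    vd_stop("duplicate sample_id in metadata", "vagidyn_validation_error")
  bad_arm <- setdiff(unique(df$arm), ARMS)
  if (length(bad_arm))
    vd_stop(sprintf("unknown arm '%s'", bad_arm[1]), "vagidyn_parse_error")
  bad_tp <- setdiff(unique(df$timepoint), TIMEPOINTS)
  if (length(bad_tp))
    vd_stop(sprintf("unknown timepoint '%s'", bad_tp[1]),
            "vagidyn_parse_error")
  key <- paste(df$participant_id, df$timepoint)
  if (anyDuplicated(key))
    vd_stop(sprintf("participant '%s' has two samples at the same timepoint",
                    df$participant_id[duplicated(key)][1]),
            "vagidyn_validation_error")
  n_arms <- tapply(df$arm, df$participant_id,
                   function(a) length(unique(a)))
  if (any(n_arms > 1))
    vd_stop(sprintf("participant '%s' appears in both arms",
                    names(n_arms)[n_arms > 1][1]),
            "vagidyn_validation_error")
  df$timepoint <- factor(df$timepoint, levels = TIMEPOINTS, ordered = TRUE)
  if (is.null(df$day)) df$day <- TIMEPOINT_DAYS[as.character(df$timepoint)]
  df <- df[order(df$participant_id, df$timepoint), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("study_design", "data.frame")
  df
}

#' Read sample metadata into a study design
#'
#' @param path TSV with columns `sample_id`, `participant_id`, `arm`,
#'   `timepoint` and optionally `day`.
#' @return A [study_design()].
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!is.null(df$day)) df$day <- as.integer(df$day)
  study_design(df)
}

#' Construct a qPCR panel
#'
#' Per-sample absolute abundance estimates (CFU/mL) for the four diagnostic
#' vaginal lactobacilli. Unmeasured species are recorded as `NA`, which is
#' treated as "absent from the panel", never as a concentration of 0.
#'
#' @param df long data frame with columns `sample_id`, `taxon` (one of
#'   `L_crispatus`, `L_iners`, `L_gasseri`, `L_jensenii`), `cfu_per_ml`.
#' @return A `qpcr_panel` data frame.
#' @export
qpcr_panel <- function(df) {
  need <- c("sample_id", "taxon", "cfu_per_ml")
  if (!all(need %in% names(df)))
    vd_stop("qPCR table must have columns sample_id, taxon, cfu_per_ml",
            "vagidyn_format_error")
  bad <- setdiff(unique(df$taxon), QPCR_SPECIES)
  if (length(bad))
    vd_stop(sprintf("unknown qPCR taxon '%s'", bad[1]), "vagidyn_parse_error")
  if (any(!is.na(df$cfu_per_ml) & df$cfu_per_ml < 0))
    vd_stop("qPCR concentrations must be >= 0", "vagidyn_validation_error")
  if (anyDuplicated(paste(df$sample_id, df$taxon)))
    vd_stop("duplicate (sample, taxon) qPCR entry", "vagidyn_validation_error")
  df <- df[, need]
  rownames(df) <- NULL
  class(df) <- c("qpcr_panel", "data.frame")
  df
}

#' Read a qPCR panel table
#'
#' @param path TSV with columns `sample_id`, `taxon`, `cfu_per_ml`; the
#'   literal string `NA` (or an empty field) marks an unmeasured species.
#' @return A [qpcr_panel()].
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  df$cfu_per_ml <- suppressWarnings(as.numeric(df$cfu_per_ml))
  qpcr_panel(df)
}

# Relative abundance row for one taxon, validating presence.
taxon_row <- function(table, taxon) {
  if (!taxon %in% rownames(table$values))
    vd_stop(sprintf("taxon '%s' not present in the table (level '%s')",
                    taxon, table$level),
            "vagidyn_usage_error")
  table$values[taxon, ]
}
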