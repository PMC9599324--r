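# Shared fixtures: tiny hand-built tables and file writers.

# taxon x sample matrix with full dimnames
mat <- function(values, taxa, samples) {
  matrix(values, nrow = length(taxa), byrow = TRUE,
         dimnames = list(taxa, samples))
}

# minimal two-taxon counts table
tiny_counts <- function() {
  abundance_table(mat(c(60, 10, 40, 90), c("t1", "t2"), c("s1", "s2")),
                  mode = "counts")
}

# subgenus-level relative composition from named values
comp <- function(...) {
  v <- c(...)
  v / sum(v)
}

# write a counts TSV (optionally with a #mode= header) and return the path
write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# small study design: n participants x chosen timepoints
toy_design <- function(participants, timepoints = TIMEPOINTS,
                       arms = NULL) {
  if (is.null(arms)) arms <- rep("placebo", length(participants))
  df <- expand.grid(participant_id = participants, timepoint = timepoints,
                    stringsAsFactors = FALSE)
  df$arm <- arms[match(df$participant_id, participants)]
  df$sample_id <- paste0(df$participant_id, "_", df$timepoint)
  study_design(df)
}

# relative subgenus-level table from a sample_id -> composition list
toy_table <- function(comps) {
  taxa <- names(comps[[1]])
  vals <- vapply(comps, function(x) x[taxa], numeric(length(taxa)))
  rownames(vals) <- taxa
  tx <- data.frame(
    taxon_id = taxa,
    genus = ifelse(taxa %in% LACTO_GROUPS, "Lactobacillus", taxa),
    subgenus_group = ifelse(taxa %in% LACTO_GROUPS, taxa, NA_character_),
    stringsAsFactors = FALSE)
  abundance_table(vals, mode = "relative", taxonomy = tx,
                  level = "subgenus_group")
}

# uniform random point on the simplex
rsimplex <- function(k) {
  e <- stats::rexp(k)
  e / sum(e)
}

# all permutations of 1..n (for brute-force path oracles)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
}

# brute-force minimum Hamiltonian path cost over all orderings
brute_force_path_cost <- function(d) {
  n <- nrow(d)
  pm <- perms(n)
  best <- Inf
  for (r in seq_len(nrow(pm))) {
    ord <- pm[r, ]
    cost <- sum(d[cbind(ord[-n], ord[-1])])
    if (cost < best) best <- cost
  }
  best
}
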