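# Plain-text interchange: FASTA for sequences, CSV for decay series and
# qPCR records, TSV for OTU tables, JSON sidecars for simulation truth.

#' Write sequences to FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write / read a flask decay series as CSV
#'
#' Columns: `flask_id`, `time_h`, `co_ppmv`, `censored`. Flask metadata
#' travels in extra constant columns.
#'
#' @param curve a [decay_curve()].
#' @param path CSV file path.
#' @return `write_decay_csv`: the path, invisibly. `read_decay_csv`: a
#'   list of `decay_curve` objects, one per flask.
#' @export
write_decay_csv <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  df <- data.frame(flask_id = curve$flask_id, time_h = curve$times_h,
                   co_ppmv = curve$co_ppmv, censored = curve$censored,
                   headspace_l = curve$headspace_l,
                   soil_dw_g = curve$soil_dw_g,
                   culture_cfu = curve$culture_cfu,
                   temperature_k = curve$temperature_k,
                   pressure_kpa = curve$pressure_kpa)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$flask_id), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    decay_curve(flask_id = d$flask_id[1L], times_h = d$time_h,
                co_ppmv = d$co_ppmv, censored = d$censored,
                headspace_l = d$headspace_l[1L],
                soil_dw_g = d$soil_dw_g[1L],
                culture_cfu = d$culture_cfu[1L],
                temperature_k = d$temperature_k[1L],
                pressure_kpa = d$pressure_kpa[1L])
  })
}

#' Write / read qPCR records as CSV
#'
#' Columns: `well`, `role` (`standard`/`unknown`), `copies`, `cq`.
#'
#' @param records data frame as produced by [simulate_qpcr_run()].
#' @param path CSV file path.
#' @return the path / the records data frame.
#' @export
write_qpcr_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_csv
#' @export
read_qpcr_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write / read an OTU table as TSV (OTUs x samples)
#'
#' @param table a `coxl_otu_table`.
#' @param path TSV file path.
#' @return the path / a `coxl_otu_table`.
#' @export
write_otu_tsv <- function(table, path) {
  stopifnot(inherits(table, "coxl_otu_table"))
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_otu_tsv
#' @param cutoff similarity cutoff recorded on the read table.
#' @export
read_otu_tsv <- function(path, cutoff = NA_real_) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  otu_table_coxl(m, cutoff = cutoff)
}

#' Write / read a simulation truth sidecar as JSON
#'
#' @param truth a `sim_truth` record.
#' @param path JSON file path.
#' @return the path / a `sim_truth`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_sim_truth(x$scenario_id, x$parameters, x$seed)
}
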