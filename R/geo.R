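#' Default vocabulary for mapping GEO time-point annotations
#'
#' GEO series deposit sample characteristics as free text; the wording of
#' time-point annotations varies between submissions. This lookup table
#' maps lower-cased annotation strings to the pipeline's canonical
#' \code{pre} / \code{post} / \code{final} vocabulary and is meant to be
#' edited or extended by the user for a particular series.
#'
#' @return a named character vector: names are annotation strings,
#'   values the canonical time points.
#' @export
geo_time_point_map <- function() {
  c("pre-operative" = "pre", "preoperative" = "pre",
    "before surgery" = "pre", "before operation" = "pre", "pre" = "pre",
    "postoperative" = "post", "post-operative" = "post",
    "after surgery" = "post", "after operation" = "post", "post" = "post",
    "recurrence" = "final", "at recurrence" = "final",
    "last observation" = "final", "final" = "final",
    "recurrence/last observation" = "final")
}

#' Read a GEO series-matrix file
#'
#' Parses the plain-text series-matrix format: \code{!Sample_*} header
#' lines for sample metadata and the block between
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end}
#' for the expression matrix. Sample characteristics of the form
#' \code{"key: value"} are scanned for patient identifiers and time-point
#' annotations; annotations are translated through \code{time_point_map}.
#' Samples whose time point cannot be mapped get \code{NA} with a warning.
#'
#' @param path path to an uncompressed series-matrix text file.
#' @param time_point_map named character vector, see
#'   \code{\link{geo_time_point_map}}.
#' @return a list with \code{matrix} (a \code{\link{signal_matrix}}, stage
#'   \code{"raw"}) and \code{samples} (a sample-sheet data.frame).
#' @export
read_geo_series_matrix <- function(path, time_point_map = geo_time_point_map()) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
    stop("malformed series matrix: missing or empty expression table block")

  split_fields <- function(line) {
    f <- strsplit(sub("^![A-Za-z_0-9]+\t?", "", line), "\t")[[1]]
    gsub('^"|"$', "", f)
  }
  grab <- function(tag) {
    hit <- grep(paste0("^!", tag, "\t"), lines[seq_len(begin - 1)], value = TRUE)
    lapply(hit, split_fields)
  }

  acc <- grab("Sample_geo_accession")
  if (!length(acc)) stop("malformed series matrix: no !Sample_geo_accession line")
  sample_ids <- acc[[1]]
  titles <- grab("Sample_title")
  titles <- if (length(titles)) titles[[1]] else sample_ids
  chars <- grab("Sample_characteristics_ch1")

  # collect per-sample "key: value" pairs across characteristics lines
  lower <- function(x) tolower(trimws(x))
  patient <- rep(NA_character_, length(sample_ids))
  tp_raw <- rep(NA_character_, length(sample_ids))
  for (row in chars) {
    if (length(row) != length(sample_ids)) next
    key <- lower(sub(":.*$", "", row))
    val <- trimws(sub("^[^:]*:", "", row))
    is_pat <- grepl("patient|subject|individual", key)
    patient[is_pat & is.na(patient)] <- val[is_pat & is.na(patient)]
    is_tp <- grepl("time|point|stage of sampling|sampling", key)
    tp_raw[is_tp & is.na(tp_raw)] <- val[is_tp & is.na(tp_raw)]
    # characteristics without a key: try the bare string as a time point
    bare <- !grepl(":", row) & lower(row) %in% names(time_point_map)
    tp_raw[bare & is.na(tp_raw)] <- row[bare & is.na(tp_raw)]
  }
  time_point <- unname(time_point_map[lower(tp_raw)])
  if (any(is.na(time_point)))
    warning("time point not mapped for ", sum(is.na(time_point)),
            " sample(s); returned as NA")
  if (all(is.na(patient))) patient <- titles

  tab <- lines[(begin + 1):(end - 1)]
  con <- textConnection(tab)
  on.exit(close(con))
  df <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gsub('^"|"$', "", as.character(df[[1]]))
  hdr <- gsub('^"|"$', "", colnames(m))
  if (!setequal(hdr, sample_ids))
    stop("malformed series matrix: table columns do not match sample accessions")
  colnames(m) <- hdr
  m <- m[, sample_ids, drop = FALSE]
  m[m < 0 & !is.na(m)] <- 0  # GEO matrices are occasionally floored below zero

  samples <- data.frame(sample_id = sample_ids, patient_id = patient,
                        time_point = time_point, title = titles,
                        stringsAsFactors = FALSE)
  list(matrix = signal_matrix(m, stage = "raw"), samples = samples)
}
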