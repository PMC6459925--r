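#' Probe panel: probe identities and classes for one array design
#'
#' A probe panel lists every probe on the array together with its class —
#' \code{"target"} (a miRNA-measuring probe), \code{"internal_control"}
#' (a miRNA probe with stable serum expression used for per-array ratio
#' standardization), or \code{"negative_control"} (a non-miRNA probe whose
#' intensity defines the per-array detection floor and background).
#' Internal controls are a subset of the miRNA-named probes; negative
#' controls carry no miRNA name.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param probe_class character vector, one of \code{"target"},
#'   \code{"internal_control"}, \code{"negative_control"}.
#' @param mirna_name character vector of miRBase-style names; must be
#'   empty (\code{""}) exactly for negative-control probes.
#' @return A \code{data.frame} of class \code{"probe_panel"} with columns
#'   \code{probe_id}, \code{probe_class}, \code{mirna_name}.
#' @examples
#' probe_panel(c("p1", "p2", "n1"),
#'             c("target", "internal_control", "negative_control"),
#'             c("hsa-miR-1260b", "hsa-miR-ic-01", ""))
#' @export
probe_panel <- function(probe_id, probe_class, mirna_name) {
  probe_id <- as.character(probe_id)
  probe_class <- as.character(probe_class)
  mirna_name <- as.character(mirna_name)
  stopifnot(length(probe_id) == length(probe_class),
            length(probe_id) == length(mirna_name))
  if (anyDuplicated(probe_id))
    stop("probe_panel: duplicated probe_id: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  bad <- setdiff(unique(probe_class),
                 c("target", "internal_control", "negative_control"))
  if (length(bad))
    stop("probe_panel: unknown probe_class: ", paste(bad, collapse = ", "))
  neg <- probe_class == "negative_control"
  if (any(mirna_name[neg] != ""))
    stop("probe_panel: negative-control probes must not carry a miRNA name")
  if (any(mirna_name[!neg] == ""))
    stop("probe_panel: target and internal-control probes need a miRNA name")
  out <- data.frame(probe_id = probe_id, probe_class = probe_class,
                    mirna_name = mirna_name, stringsAsFactors = FALSE)
  class(out) <- c("probe_panel", "data.frame")
  out
}

#' @export
print.probe_panel <- function(x, ...) {
  tab <- table(x$probe_class)
  cat("Probe panel:", nrow(x), "probes (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Read / write a probe panel as tab-separated text
#'
#' Columns \code{probe_id}, \code{probe_class}, \code{mirna_name};
#' UTF-8, tab-separated, with a header row. Row order is preserved.
#'
#' @param path file path.
#' @param panel a \code{\link{probe_panel}}.
#' @return \code{read_probe_panel} returns a \code{probe_panel};
#'   \code{write_probe_panel} returns \code{path} invisibly.
#' @export
read_probe_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("probe_id", "probe_class", "mirna_name")
  if (!all(need %in% names(df)))
    stop("probe panel file must have columns: ", paste(need, collapse = ", "))
  probe_panel(df$probe_id, df$probe_class, df$mirna_name)
}

#' @rdname read_probe_panel
#' @export
write_probe_panel <- function(panel, path) {
  stopifnot(inherits(panel, "probe_panel"))
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

panel_probes <- function(panel, classes) {
  panel$probe_id[panel$probe_class %in% classes]
}
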