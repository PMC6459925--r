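MODEL_FORMAT <- "mirna-recurrence-index"
MODEL_VERSION <- 1L

#' Serialize / deserialize a recurrence-predictive index model
#'
#' Models are written as a versioned, human-readable JSON document so that
#' a published index (member miRNAs, coefficients, intercept, cut-off and
#' training metrics) remains auditable as plain text. Numbers are written
#' at full precision; the round trip is lossless.
#'
#' @param model an \code{\link{flda}} model (or any object with
#'   \code{members}, \code{coefficients}, \code{intercept}, \code{cutoff}
#'   and optional \code{metrics}).
#' @param path file path.
#' @return \code{read_model} returns the model (class \code{"flda"});
#'   \code{write_model} returns \code{path} invisibly.
#' @export
write_model <- function(model, path) {
  if (length(model$members) < 1)
    stop("refusing to write a model with no member miRNAs")
  if (length(model$members) != length(model$coefficients))
    stop("model has ", length(model$coefficients), " coefficients for ",
         length(model$members), " members")
  if (!all(is.finite(c(model$coefficients, model$intercept, model$cutoff))))
    stop("model coefficients, intercept and cutoff must be finite")
  doc <- list(
    format = MODEL_FORMAT,
    version = MODEL_VERSION,
    members = as.character(model$members),
    coefficients = unname(as.numeric(model$coefficients)),
    intercept = as.numeric(model$intercept),
    cutoff = as.numeric(model$cutoff),
    metrics = as.list(model$metrics)
  )
  # digits = I(17): enough significant digits for a bitwise double round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, MODEL_FORMAT))
    stop("not a recurrence-index model file: format '", doc$format, "'")
  if (!identical(as.integer(doc$version), MODEL_VERSION))
    stop("model file version ", doc$version,
         " not supported (expected ", MODEL_VERSION, ")")
  new_flda(members = doc$members,
           coefficients = stats::setNames(doc$coefficients, doc$members),
           intercept = doc$intercept, cutoff = doc$cutoff,
           metrics = if (length(doc$metrics)) doc$metrics else NULL)
}
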