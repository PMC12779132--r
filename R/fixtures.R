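# Case-record serialization: JSON Lines (one record per line) plus a JSON
# manifest of the generative parameters and splits.

record_to_json <- function(rec) {
  obj <- list(case_id = rec$case_id)
  obj$image <- if (is.null(rec$image)) NULL else
    lapply(seq_len(nrow(rec$image)), function(i) rec$image[i, ])
  obj$text <- if (is.null(rec$text)) NULL else rec$text
  obj$structured <- if (is.null(rec$structured)) NULL else rec$structured
  obj$labels <- rec$labels
  obj$severity <- rec$severity
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
}

json_to_record <- function(line) {
  obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
  img <- obj$image
  if (!is.null(img)) {
    if (is.character(img)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG image paths requires the 'png' package")
      img <- png::readPNG(img)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
    } else if (is.list(img)) {
      img <- do.call(rbind, img)
    }
    img <- as.matrix(img)
  }
  case_record(obj$case_id, image = img,
              text = if (length(obj$text)) obj$text else NULL,
              structured = obj$structured, labels = obj$labels,
              severity = obj$severity)
}

#' Write case records as JSON Lines
#'
#' One JSON object per line: id, image as nested array (or a PNG file path),
#' text token list, structured vector, labels, severity. Full numeric
#' precision is kept so a read/write round trip is exact.
#'
#' @param records list of \code{\link{case_record}} objects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_case_records <- function(records, path) {
  writeLines(vapply(records, record_to_json, ""), path)
  invisible(path)
}

#' @rdname write_case_records
#' @export
read_case_records <- function(path) {
  lapply(readLines(path), json_to_record)
}

#' Write / read a synthetic dataset as plain-text fixtures
#'
#' \code{write_fixtures} writes \code{records.jsonl} plus
#' \code{manifest.json} (generator config, true class means, image templates,
#' token distributions, class assignment and split indices) under
#' \code{path}; \code{read_fixtures} reconstructs the dataset so that
#' \code{read_fixtures(write_fixtures(d))} is an identity.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param path directory (created if needed).
#' @return \code{write_fixtures}: \code{path}, invisibly;
#'   \code{read_fixtures}: the \code{synthetic_dataset}.
#' @export
write_fixtures <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_case_records(dataset$records, file.path(path, "records.jsonl"))
  p <- dataset$params
  manifest <- list(
    config = unclass(p$config),
    class_means = apply(p$class_means, 1L, identity, simplify = FALSE),
    templates = lapply(p$templates, function(tm)
      lapply(seq_len(nrow(tm)), function(i) tm[i, ])),
    token_probs = apply(p$token_probs, 1L, identity, simplify = FALSE),
    classes = p$classes,
    splits = dataset$splits)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fixtures
#' @export
read_fixtures <- function(path) {
  records <- read_case_records(file.path(path, "records.jsonl"))
  m <- jsonlite::read_json(file.path(path, "manifest.json"),
                           simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  cfg_list <- as.list(m$config)[names(formals(generator_config))]
  cfg_list$split <- unlist(cfg_list$split)
  cfg <- do.call(generator_config, cfg_list)
  structure(list(records = records,
                 params = list(config = cfg,
                               class_means = as_mat(m$class_means),
                               templates = if (is.array(m$templates) &&
                                               length(dim(m$templates)) == 3L)
                                 lapply(seq_len(dim(m$templates)[1]), function(c)
                                   m$templates[c, , ])
                               else lapply(m$templates, as_mat),
                               token_probs = as_mat(m$token_probs),
                               classes = as.integer(m$classes)),
                 splits = lapply(m$splits, as.integer)),
            class = "synthetic_dataset")
}
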