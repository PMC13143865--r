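MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize / load a vascular age model as JSON
#'
#' Schema: `{version, sex, tag, markers[], log_markers[],
#' standardization{mean, sd, log_markers}, pca{loadings[][], explained[],
#' sign_convention}, kdm{k[], q[], s[], retained[], s_floored[]},
#' provenance{n_train, seed}}`. Numbers are written with 17 significant
#' digits so a save/load round trip reproduces biological ages bitwise on
#' the same platform.
#'
#' @param model A `vascular_age_model`.
#' @param path Optional file path; when `NULL`, the JSON string is
#'   returned.
#' @return `serialize_model`: the JSON string (invisibly when written to a
#'   file). `load_model`: the reconstructed model.
#' @export
serialize_model <- function(model, path = NULL) {
  x <- list(
    version = model$version, sex = model$sex, tag = model$tag,
    markers = model$markers, log_markers = model$log_markers,
    standardization = list(mean = as.list(model$standardization$mean),
                           sd = as.list(model$standardization$sd),
                           log_markers = model$standardization$log_markers),
    pca = list(loadings = unname(model$pca$loadings),
               explained = model$pca$explained,
               sign_convention = model$pca$sign_convention),
    kdm = list(k = model$kdm$k, q = model$kdm$q, s = model$kdm$s,
               retained = model$kdm$retained,
               s_floored = model$kdm$s_floored, n = model$kdm$n),
    provenance = model$provenance
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname serialize_model
#' @param json JSON string or path to a JSON file.
#' @export
load_model <- function(json) {
  x <- tryCatch(jsonlite::fromJSON(json, simplifyVector = TRUE),
                error = function(e) stopf("cannot parse model JSON: %s",
                                          conditionMessage(e)))
  req <- c("version", "sex", "tag", "markers", "standardization", "pca", "kdm")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L)
    stopf("model JSON missing field(s): %s", paste(miss, collapse = ", "))
  if (!identical(x$version, MODEL_SCHEMA_VERSION))
    stopf("model schema version '%s' not supported (expected '%s')",
          x$version, MODEL_SCHEMA_VERSION)
  for (f in c("k", "q", "s"))
    if (is.null(x$kdm[[f]])) stopf("model JSON kdm block missing '%s'", f)
  markers <- as.character(x$markers)
  load <- matrix(unlist(x$pca$loadings), nrow = length(markers), byrow = FALSE)
  # jsonlite parses a matrix row-major into a row-major array of arrays
  if (is.matrix(x$pca$loadings)) load <- x$pca$loadings
  dimnames(load) <- list(markers, paste0("PC", seq_len(ncol(load))))
  std <- structure(list(markers = markers,
                        mean = unlist(x$standardization$mean)[markers],
                        sd = unlist(x$standardization$sd)[markers],
                        log_markers = as.character(unlist(x$standardization$log_markers))),
                   class = "standardizer")
  rot <- structure(list(loadings = load, explained = as.numeric(x$pca$explained),
                        markers = markers,
                        sign_convention = x$pca$sign_convention %||% "positive"),
                   class = "pca_rotation")
  kdm <- structure(list(k = as.numeric(x$kdm$k), q = as.numeric(x$kdm$q),
                        s = as.numeric(x$kdm$s),
                        retained = as.integer(x$kdm$retained),
                        s_floored = as.logical(x$kdm$s_floored),
                        n = x$kdm$n), class = "kdm_params")
  if (any(kdm$s <= 0) || anyNA(kdm$s)) stopf("invalid s values in model JSON")
  structure(list(version = x$version, sex = x$sex, tag = x$tag,
                 markers = markers,
                 log_markers = as.character(unlist(x$log_markers)),
                 standardization = std, pca = rot, kdm = kdm,
                 provenance = as.list(x$provenance)),
            class = "vascular_age_model")
}
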