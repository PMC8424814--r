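#' Save and load a fitted outcome model as JSON
#'
#' One self-contained JSON document: feature schema, frozen scaling,
#' bandwidth, exemplar rows, targets and training metadata — enough to
#' reproduce predictions exactly on another machine.
#'
#' @param model A `cpi_outcome_model`.
#' @param path File path.
#' @return `read_outcome_model_json()` returns the restored model;
#'   `write_outcome_model_json()` returns `path` invisibly.
#' @export
write_outcome_model_json <- function(model, path) {
  g <- model$grnn
  doc <- list(
    format = "cpimpact_outcome_model_v1",
    outcome = model$outcome, task = model$task,
    scaling_method = model$scaling_method,
    schema = model$schema, scaling = model$scaling,
    sigma = g$sigma,
    exemplars = unname(apply(g$exemplars, 1L, as.numeric, simplify = FALSE)),
    feature_names = colnames(g$exemplars),
    targets = g$targets,
    class_levels = g$class_levels, class_freq = g$class_freq,
    metadata = list(cycles = g$cycles, seconds = g$seconds,
                    criterion = g$criterion, stop_reason = g$stop_reason))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_outcome_model_json
#' @export
read_outcome_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "cpimpact_outcome_model_v1")) {
    stop("not a cpimpact outcome-model document: ", path)
  }
  ex <- doc$exemplars
  if (is.list(ex)) ex <- do.call(rbind, ex)
  colnames(ex) <- doc$feature_names
  g <- structure(list(
    task = doc$task, exemplars = ex,
    targets = if (doc$task == "continuous") as.numeric(doc$targets)
              else as.character(doc$targets),
    sigma = doc$sigma,
    class_levels = doc$class_levels, class_freq = doc$class_freq,
    schema = doc$schema, scaling = doc$scaling,
    cycles = doc$metadata$cycles, seconds = doc$metadata$seconds,
    criterion = doc$metadata$criterion,
    stop_reason = doc$metadata$stop_reason), class = "grnn")
  structure(list(grnn = g, outcome = doc$outcome, task = doc$task,
                 schema = as.data.frame(doc$schema),
                 scaling = as.data.frame(doc$scaling),
                 scaling_method = doc$scaling_method),
            class = "cpi_outcome_model")
}
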