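# Text checkpoints: model and augmenter parameters serialized as JSON with
# explicit dimensions, so checkpoints survive text-only storage and diff
# cleanly.

serialize_tree <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) return(lapply(x, serialize_tree))
  list(.dim = shape_of(x), .data = as.numeric(x))
}

deserialize_tree <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.null(x$.data)) {
    v <- as.numeric(x$.data)
    d <- as.integer(unlist(x$.dim))
    if (length(d) > 1L) dim(v) <- d
    return(v)
  }
  lapply(x, deserialize_tree)
}

#' Save a dual-branch model to a JSON checkpoint
#'
#' Gate parameters are stored under `dag/{stage}/{direction}/{W,b,U,e}`.
#' @param model a [dual_branch_model()]
#' @param path output file
#' @export
save_model <- function(model, path) {
  gates <- lapply(model$gates, function(g) {
    list(am = serialize_tree(unclass(g$am)), ma = serialize_tree(unclass(g$ma)))
  })
  payload <- list(
    meta = list(num_classes = model$num_classes,
                image_size = model$image_size, stages = model$stages,
                channels = model$channels, grid = model$grid),
    main_backbone = serialize_tree(model$main_backbone),
    aux_backbone = serialize_tree(model$aux_backbone),
    main_head = serialize_tree(model$main_head),
    aux_head = serialize_tree(model$aux_head),
    dag = gates)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a dual-branch model from a JSON checkpoint
#'
#' @param path checkpoint file written by [save_model()]
#' @return a [dual_branch_model()]
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path)
  meta <- p$meta
  model <- dual_branch_model(num_classes = meta$num_classes,
                             image_size = meta$image_size,
                             stages = meta$stages,
                             channels = as.integer(unlist(meta$channels)))
  model$main_backbone <- deserialize_tree(p$main_backbone)
  model$aux_backbone <- deserialize_tree(p$aux_backbone)
  model$main_head <- deserialize_tree(p$main_head)
  model$aux_head <- deserialize_tree(p$aux_head)
  model$gates <- lapply(p$dag, function(g) {
    list(am = structure(deserialize_tree(g$am), class = "gate_params"),
         ma = structure(deserialize_tree(g$ma), class = "gate_params"))
  })
  model
}
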