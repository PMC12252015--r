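# Weight checkpoints: a single-file archive of named arrays (parameters and
# batch-norm running buffers); names are the stable dotted module paths.

#' Save / load model weights
#'
#' @param model An `rfc_model` or any module tree.
#' @param path Checkpoint file path (RDS archive of named arrays).
#' @export
save_checkpoint <- function(model, path) {
  buffers <- list()
  walk_modules(model, function(mod, p) {
    for (nm in names(mod$buffers))
      buffers[[paste(p, nm, sep = ".")]] <<- mod$buffers[[nm]]
  })
  saveRDS(list(params = named_params(model), buffers = buffers,
               cfg = unclass(model$cfg), num_classes = model$num_classes),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  missing <- setdiff(names(ck$params), names(named_params(model)))
  if (length(missing))
    stopf("checkpoint does not match model (first unknown array: %s)", missing[1])
  set_named_params(model, ck$params)
  walk_modules(model, function(mod, p) {
    for (nm in names(mod$buffers)) {
      key <- paste(p, nm, sep = ".")
      if (!is.null(ck$buffers[[key]])) mod$buffers[[nm]] <- ck$buffers[[key]]
    }
  })
  invisible(model)
}
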