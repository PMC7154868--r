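#' Write / read a simulation configuration file
#'
#' JSON file holding a [selection_config()] and a [binding_model()], the two
#' objects that fully define a simulated Bind-n-Seq experiment.
#'
#' @param config a [selection_config()].
#' @param model a [binding_model()].
#' @param path file path.
#' @return `path` (writer); a list with `config` and `model` (reader).
#' @export
write_config <- function(config, model, path) {
  stopifnot(inherits(config, "selection_config"), inherits(model, "binding_model"))
  obj <- list(
    selection = unclass(config),
    binding_model = list(
      motif_affinities = as.list(model$motif_affinities),
      background_affinity = model$background_affinity,
      combine_rule = model$combine_rule
    )
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  s <- obj$selection
  config <- selection_config(
    protein_concentrations = as.numeric(s$protein_concentrations),
    rna_concentration = as.numeric(s$rna_concentration),
    read_length = as.integer(s$read_length),
    n_input_reads = as.integer(s$n_input_reads),
    n_pulldown_reads = as.integer(s$n_pulldown_reads),
    seed = as.integer(s$seed)
  )
  bm <- obj$binding_model
  model <- binding_model(unlist(bm$motif_affinities),
                         background_affinity = as.numeric(bm$background_affinity),
                         combine_rule = bm$combine_rule)
  list(config = config, model = model)
}
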