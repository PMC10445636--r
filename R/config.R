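# Run configuration: a nested JSON (or YAML) document mirroring the
# trainer's semantics, validated against a schema template with
# JSON-path-style error locations, plus model serialization ("freezing")
# and the command-line interface.

config_template <- function() {
  list(
    model = list(
      type_map = character(),
      descriptor = list(
        type = "se_e2_a", rcut = 5.5, rcut_smth = 2.0, sel = 20L,
        neuron = c(25L, 50L, 100L), axis_neuron = 16L,
        activation_function = "tanh", resnet_dt = FALSE,
        routing = "pair", mode = "full",
        attn_layer = 2L, attn = 64L, attn_dotr = TRUE,
        hybrid_list = list()),
      fitting_net = list(
        neuron = c(240L, 240L, 240L), activation_function = "tanh",
        resnet_dt = FALSE, numb_aparam = 0L, numb_fparam = 0L),
      type_embedding = list(neuron = c(8L)),
      share_fitting = FALSE),
    learning_rate = list(start_lr = 1e-3, stop_lr = 1e-5,
                         decay_steps = 500L),
    loss = list(start_pref_e = 0.02, limit_pref_e = 1,
                start_pref_f = 1000, limit_pref_f = 1,
                start_pref_v = 0, limit_pref_v = 0,
                relative_f = NULL),
    training = list(numb_steps = 1000L, batch_size = 1L, seed = 1L,
                    systems = character(), validation_fraction = 0.05,
                    disp_freq = 100L)
  )
}

check_config_keys <- function(cfg, template, path = "$") {
  if (!is.list(cfg)) return(invisible(TRUE))
  nm <- names(cfg)
  if (is.null(nm)) return(invisible(TRUE))
  known <- names(template)
  for (k in nm) {
    if (!k %in% known)
      stop("unknown configuration key at ", path, ".", k, call. = FALSE)
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      check_config_keys(cfg[[k]], template[[k]], paste0(path, ".", k))
  }
  invisible(TRUE)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
                     is.list(user[[k]]))
      merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' Parse and validate a run configuration
#'
#' Reads a JSON (or YAML, when the `yaml` package is available)
#' configuration, rejects unknown keys with their location, and fills
#' defaults.
#'
#' @param path file path, or a named list already in memory.
#' @return the completed configuration list.
#' @export
parse_config <- function(path) {
  user <- if (is.list(path)) path
  else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  tmpl <- config_template()
  check_config_keys(user, tmpl, "$")
  cfg <- merge_config(tmpl, user)
  if (length(cfg$model$type_map) == 0L)
    stop("configuration error at $.model.type_map: at least one species ",
         "is required", call. = FALSE)
  cfg
}

#' Serialize a configuration to JSON
#' @param cfg configuration list.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

descriptor_from_config <- function(d) {
  if (identical(d$type, "hybrid"))
    return(descriptor_config("hybrid",
      children = lapply(d$hybrid_list, descriptor_from_config)))
  descriptor_config(d$type, rcut = d$rcut, rcut_smth = d$rcut_smth,
                    sel = d$sel, neuron = d$neuron,
                    axis_neuron = d$axis_neuron,
                    activation = d$activation_function,
                    resnet_dt = d$resnet_dt, routing = d$routing,
                    mode = d$mode, attn_layer = d$attn_layer,
                    attn_dk = d$attn, attn_dotr = d$attn_dotr)
}

#' Build an energy model from a configuration
#' @param cfg a [parse_config()] result.
#' @param seed overrides `training.seed` when not `NULL`.
#' @return a `dp_energy_model`.
#' @export
model_from_config <- function(cfg, seed = NULL) {
  f <- cfg$model$fitting_net
  energy_model(cfg$model$type_map,
               descriptor = descriptor_from_config(cfg$model$descriptor),
               fitting = fitting_config(neuron = f$neuron,
                                        activation = f$activation_function,
                                        resnet_dt = f$resnet_dt,
                                        numb_aparam = f$numb_aparam,
                                        numb_fparam = f$numb_fparam),
               type_embed_neuron = cfg$model$type_embedding$neuron,
               share_fitting = isTRUE(cfg$model$share_fitting),
               seed = seed %||% cfg$training$seed)
}

#' Estimate `sel` from data
#'
#' Scans the maximum per-species neighbor count over the frames and adds a
#' 10 percent margin, the package's simple default in place of automatic
#' neighbor-size heuristics.
#'
#' @param ds a `dp_system`.
#' @param rcut cutoff radius.
#' @param nt number of species.
#' @return integer vector of length `nt`.
#' @export
estimate_sel <- function(ds, rcut, nt) {
  mx <- rep(0L, nt)
  for (fr in ds$frames) {
    nl <- build_neighbor_list(fr$frame, rcut)
    for (a in seq_len(fr$frame$n_atoms)) {
      rows <- nl_rows(nl, a)
      if (!length(rows)) next
      cnt <- tabulate(nl$alpha_j[rows] + 1L, nt)
      mx <- pmax(mx, cnt)
    }
  }
  as.integer(ceiling(mx * 1.1))
}

#' Save ("freeze") a model
#'
#' Writes the model container — configuration, type map and all parameters
#' — as one file.
#'
#' @param model a `dp_energy_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a frozen model
#' @param path a [save_model()] file.
#' @return the model.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "dp_energy_model"))
    stop(path, " is not a frozen energy model", call. = FALSE)
  m
}
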