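#' Save a model checkpoint
#'
#' Self-describing container (an RDS file of a named list) holding the
#' weights, architecture numbers, standardizer tables, training
#' configuration and a content hash of the configuration.
#'
#' @param model A trained GAN model ([train_gan()]) or a
#'   [train_handedness_selector()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  payload <- if (inherits(model, "handedness_selector"))
    list(kind = "handedness_selector", weights = model$weights,
         arch = unclass(model$arch),
         train_accuracy = model$train_accuracy,
         certified = model$certified)
  else
    list(kind = "gan", G = model$G, G_ema = model$G_ema, D = model$D,
         arch_G = unclass(model$arch_G), arch_D = unclass(model$arch_D),
         std = unclass(model$std), x_t = model$x_t, log = model$log,
         cfg = if (!is.null(model$cfg)) unclass(model$cfg) else NULL)
  payload$config_hash <- config_hash(payload[setdiff(names(payload),
                                                     c("G", "D", "weights",
                                                       "log"))])
  payload$package_version <- as.character(utils::packageVersion("idpgem"))
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return The reconstructed model object.
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (identical(payload$kind, "handedness_selector")) {
    structure(list(weights = payload$weights,
                   arch = structure(payload$arch,
                                    class = "generator_architecture"),
                   train_accuracy = payload$train_accuracy,
                   certified = payload$certified),
              class = "handedness_selector")
  } else {
    model <- list(
      arch_G = structure(payload$arch_G, class = "generator_architecture"),
      arch_D = structure(payload$arch_D,
                         class = "discriminator_architecture"),
      G = payload$G, G_ema = payload$G_ema, D = payload$D,
      sn_env = setNames(lapply(names(payload$D),
                               function(k) new.env(parent = emptyenv())),
                        names(payload$D)),
      std = structure(payload$std, class = "feature_standardizer"),
      x_t = payload$x_t, log = payload$log)
    if (!is.null(payload$cfg))
      model$cfg <- structure(payload$cfg, class = "training_configuration")
    model
  }
}

# order-stable hash of a plain list (no external digest dependency)
config_hash <- function(x) {
  txt <- paste(utils::capture.output(dput(x)), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
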