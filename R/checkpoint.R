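# Model persistence: a single archive holding the config and named
# parameter tensors, versioned with a format tag and shape-audited on
# load.

CKPT_FORMAT <- "seqddg-ckpt-1"

expected_shapes <- function(cfg) {
  h <- cfg$hidden_size; d <- 3L * h; f <- cfg$fc_sizes
  sh <- list()
  for (b in 1:3) {
    sh[[paste0("conv", b, "_W")]] <- c(cfg$kernel_sizes[b] * 40L, 2L * h)
    sh[[paste0("conv", b, "_b")]] <- 2L * h
  }
  sh$ln_g <- d; sh$ln_b <- d
  for (pre in c("sa", "ma"))
    for (w in c("Wq", "Wk", "Wv", "Wo"))
      sh[[paste0(pre, "_", w)]] <- c(d, d)
  sh$fc1_W <- c(4L * d, f[1]); sh$fc1_b <- f[1]
  sh$fc2_W <- c(f[1], f[2]);   sh$fc2_b <- f[2]
  sh$fc3_W <- c(f[2], f[3]);   sh$fc3_b <- f[3]
  sh$out_W <- c(f[3], 1L);     sh$out_b <- 1L
  sh
}

#' Audit a model's parameter shapes and values
#'
#' Checks that every parameter tensor exists, has the shape implied by
#' the configuration, and contains only finite values.
#'
#' @param model A `ddg_model`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_model_shapes <- function(model) {
  sh <- expected_shapes(model$config)
  for (nm in names(sh)) {
    p <- model$par[[nm]]
    if (is.null(p)) stop("missing parameter '", nm, "'", call. = FALSE)
    got <- if (is.matrix(p)) dim(p) else length(p)
    if (!identical(as.integer(got), as.integer(sh[[nm]])))
      stop(sprintf("parameter '%s' has shape (%s), expected (%s)", nm,
                   paste(got, collapse = ","),
                   paste(sh[[nm]], collapse = ",")), call. = FALSE)
    if (!all(is.finite(p)))
      stop("non-finite values in parameter '", nm, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Save a model checkpoint
#' @param model A `ddg_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ddg_model"))
  saveRDS(list(format = CKPT_FORMAT, config = unclass(model$config),
               par = model$par), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Checkpoint file written by [save_model()].
#' @return A `ddg_model`, shape-audited.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, CKPT_FORMAT))
    stop("unrecognized checkpoint format: ", obj$format %||% "<none>",
         call. = FALSE)
  model <- structure(list(config = structure(obj$config,
                                             class = "ddg_model_config"),
                          par = obj$par), class = "ddg_model")
  check_model_shapes(model)
  model
}
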