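#' Run configuration for the bi-random-walk pipeline
#'
#' Collects every tunable parameter of the prediction pipeline with the
#' defaults used throughout the package.
#'
#' @param alpha Walk-continuation probability in `[0, 1]`; `1 - alpha` is the
#'   probability of restarting from the seed distribution at each step.
#' @param ew Weight of the Spearman expression similarity in the lncRNA
#'   similarity fusion, in `[0, 1]`; the interaction-profile kernel gets
#'   `1 - ew`. Only pairs where both lncRNAs carry expression profiles are
#'   affected.
#' @param gamma_l_prime,gamma_d_prime Bandwidth scaling of the Gaussian
#'   interaction-profile kernels for lncRNAs and diseases (positive; the
#'   effective bandwidth divides by the mean squared profile norm).
#' @param c,d Parameters of the logistic transform applied to the disease
#'   kernel, `1 / (1 + exp(c * k + d))`. The defaults `c = -15`,
#'   `d = log(9999)` map a kernel value of 0 to 1e-4 and keep the transform
#'   strictly increasing.
#' @param tol Convergence threshold on the maximum absolute change between
#'   successive score matrices.
#' @param max_iter Iteration cap for the walk; hitting it flags
#'   non-convergence rather than raising an error.
#'
#' @return A list of class `lnc_config`.
#' @export
#' @examples
#' cfg <- lnc_config(alpha = 0.8)
#' cfg$alpha
lnc_config <- function(alpha = 0.9, ew = 0.5,
                       gamma_l_prime = 1, gamma_d_prime = 1,
                       c = -15, d = log(9999),
                       tol = 1e-10, max_iter = 1000L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(ew), length(ew) == 1L, ew >= 0, ew <= 1,
            is.numeric(gamma_l_prime), gamma_l_prime > 0,
            is.numeric(gamma_d_prime), gamma_d_prime > 0,
            is.numeric(c), length(c) == 1L,
            is.numeric(d), length(d) == 1L,
            is.numeric(tol), tol > 0,
            is.numeric(max_iter), max_iter >= 1)
  structure(list(alpha = alpha, ew = ew,
                 gamma_l_prime = gamma_l_prime, gamma_d_prime = gamma_d_prime,
                 c = c, d = d, tol = tol, max_iter = as.integer(max_iter)),
            class = "lnc_config")
}

#' Read a run configuration file
#'
#' Accepts either a YAML mapping or flat `key = value` lines; keys are the
#' arguments of [lnc_config()]. Unknown keys raise an error, missing keys
#' fall back to the defaults.
#'
#' @param path Path to the configuration file.
#' @return An `lnc_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  vals <- tryCatch(yaml::yaml.load(paste(lines, collapse = "\n")),
                   error = function(e) NULL)
  if (!is.list(vals) || is.null(names(vals))) {
    # key = value fallback
    parts <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      abort(paste0("cannot parse config line: '", lines[which(bad)[1]], "'"))
    }
    vals <- lapply(parts, function(p) {
      v <- trimws(p[2])
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) eval(parse(text = v), envir = baseenv()) else num
    })
    names(vals) <- trimws(vapply(parts, `[`, "", 1))
  }
  # YAML 1.1 leaves scientific notation like "1e-8" as a string
  vals <- lapply(vals, function(v) {
    if (is.character(v) && !is.na(suppressWarnings(as.numeric(v)))) {
      as.numeric(v)
    } else v
  })
  known <- names(formals(lnc_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  do.call(lnc_config, vals)
}
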