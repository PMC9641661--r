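#' Configuration files and tabular serialisation
#'
#' Runs are driven by a YAML configuration with sections `basic_model`,
#' `extended_model`, `profile`, `locus_model`, `solver` and
#' `experiment`, plus a global `seed` and an optional `output_dir`.
#' Unknown keys are an error, never silently ignored, and every numeric
#' field is validated by the constructor of the object it configures.
#' Trajectories, fixed points and summaries are written as
#' tab-separated text with a comment header carrying the package
#' version and the effective seed.
#'
#' @name cli_io
NULL

.config_schema <- list(
  basic_model = c("alpha_h", "mu_h", "alpha_X", "mu_X"),
  extended_model = c("alpha_Y", "beta_Y", "mu_Y",
                     "y_on_h", "h_on_y", "y_self", "gate_basal_only"),
  profile = c("kind", "m0", "m1", "t0", "t1", "steps",
              "noise_amplitude", "noise_correlation_time"),
  locus_model = c("n_cells", "loci", "decay_rate", "basal",
                  "t0", "t1", "dt"),
  solver = c("rtol", "atol", "max_step"),
  experiment = c("name", "m0", "m_end", "t_change", "first_fold",
                 "t_end", "amplitude", "correlation_time", "n_seeds",
                 "p1_values"),
  seed = NULL, output_dir = NULL
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
}

hill_from_config <- function(x, name) {
  if (is.null(x)) return(NULL)
  check_keys(x, c("n", "p0"), paste0("extended_model$", name))
  hill_spec(x$n, x$p0)
}

#' Parse and validate a run configuration
#'
#' Missing sections and fields fall back to the package defaults (the
#' reference parameter set, solver tolerances rtol = 1e-8 and
#' atol = 1e-10, and seed 1). The fully resolved configuration is
#' returned, so writing it back out with [write_config()] echoes the
#' effective settings.
#'
#' @param path path to a YAML configuration file.
#' @return A `run_config` list with elements `basic`, `extended`,
#'   `profile` (an [mir9_profile] or `NULL`), `locus` (a
#'   [locus_config()]), `solver`, `experiment`, `seed`, `output_dir`
#'   and `raw` (the resolved YAML structure).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # keep boolean-looking scalars (incl. the Hill key 'n') as strings:
  # YAML 1.1 would otherwise read the key 'n' as FALSE
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  check_keys(raw, names(.config_schema), "config")
  for (sec in names(.config_schema)) {
    if (!is.null(raw[[sec]]) && !is.null(.config_schema[[sec]]))
      check_keys(raw[[sec]], .config_schema[[sec]], sec)
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  bm <- raw$basic_model
  basic <- tryCatch(
    do.call(basic_params, if (is.null(bm)) list() else bm),
    error = function(e) stop("basic_model: ", conditionMessage(e), call. = FALSE))

  em <- raw$extended_model
  ext_args <- list(basic = basic)
  if (!is.null(em)) {
    for (k in c("alpha_Y", "beta_Y", "mu_Y"))
      if (!is.null(em[[k]])) ext_args[[k]] <- em[[k]]
    if (!is.null(em$gate_basal_only))
      ext_args$gate_basal_only <- config_bool(em$gate_basal_only,
                                              "gate_basal_only")
    for (k in c("y_on_h", "h_on_y", "y_self")) {
      hs <- hill_from_config(em[[k]], k)
      if (!is.null(hs)) ext_args[[paste0("hill_", k)]] <- hs
    }
  }
  extended <- tryCatch(
    do.call(extended_params, ext_args),
    error = function(e) stop("extended_model: ", conditionMessage(e), call. = FALSE))

  prof <- NULL
  pr <- raw$profile
  if (!is.null(pr)) {
    kind <- if (is.null(pr$kind)) "constant" else pr$kind
    prof <- switch(
      kind,
      constant = make_constant(pr$m0, pr$t0 %||% 0, pr$t1 %||% 100),
      linear = make_linear(pr$m0, pr$m1, pr$t0 %||% 0, pr$t1 %||% 100),
      steps = make_steps(pr$m0,
                         do.call(rbind, lapply(pr$steps, function(s)
                           data.frame(t = s$t, fold = s$fold))),
                         t0 = pr$t0 %||% 0, t1 = pr$t1),
      stop("profile: unknown kind '", kind, "'", call. = FALSE))
    if (!is.null(pr$noise_amplitude) && pr$noise_amplitude > 0)
      prof <- make_fluctuating(prof, pr$noise_amplitude,
                               pr$noise_correlation_time %||% 2,
                               component_seed(seed, "profile_noise"))
  }

  lm_ <- raw$locus_model
  locus_args <- list(seed = component_seed(seed, "locus_model"))
  if (!is.null(lm_)) {
    for (k in setdiff(.config_schema$locus_model, "loci"))
      if (!is.null(lm_[[k]])) locus_args[[k]] <- lm_[[k]]
    if (!is.null(lm_$loci))
      locus_args$loci <- do.call(rbind, lapply(lm_$loci, function(l) {
        check_keys(l, c("name", "onset_mean", "onset_sd", "production_rate"),
                   "locus_model$loci")
        as.data.frame(l)
      }))
  }
  locus <- tryCatch(
    do.call(locus_config, locus_args),
    error = function(e) stop("locus_model: ", conditionMessage(e), call. = FALSE))

  sv <- raw$solver
  solver <- tryCatch(
    do.call(solver_settings, if (is.null(sv)) list() else sv),
    error = function(e) stop("solver: ", conditionMessage(e), call. = FALSE))

  resolved <- list(
    basic_model = unclass(basic),
    extended_model = list(alpha_Y = extended$alpha_Y,
                          beta_Y = extended$beta_Y, mu_Y = extended$mu_Y,
                          y_on_h = unclass(extended$hill_y_on_h),
                          h_on_y = unclass(extended$hill_h_on_y),
                          y_self = unclass(extended$hill_y_self),
                          gate_basal_only = extended$gate_basal_only),
    profile = pr,
    locus_model = list(n_cells = locus$n_cells,
                       loci = lapply(seq_len(nrow(locus$loci)), function(i)
                         as.list(locus$loci[i, ])),
                       decay_rate = locus$decay_rate, basal = locus$basal,
                       t0 = locus$t0, t1 = locus$t1, dt = locus$dt),
    solver = unclass(solver),
    experiment = raw$experiment,
    seed = seed,
    output_dir = raw$output_dir
  )
  structure(list(basic = basic, extended = extended, profile = prof,
                 locus = locus, solver = solver,
                 experiment = raw$experiment, seed = seed,
                 output_dir = raw$output_dir, raw = resolved),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_bool <- function(x, field) {
  if (is.logical(x)) return(isTRUE(x))
  if (is.character(x) && tolower(x) %in% c("true", "yes", "on")) return(TRUE)
  if (is.character(x) && tolower(x) %in% c("false", "no", "off")) return(FALSE)
  stop("'", field, "' must be true or false", call. = FALSE)
}

#' Write the resolved configuration back to YAML
#'
#' @param config a `run_config` from [parse_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- config$raw
  raw <- raw[!vapply(raw, is.null, logical(1))]
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Path to the shipped reference configuration
#'
#' @return File path of the reference YAML configuration.
#' @export
reference_config_path <- function() {
  system.file("extdata", "reference_config.yaml", package = "mir9step",
              mustWork = TRUE)
}

tsv_header <- function(seed) {
  sprintf("# mir9step %s\tseed=%s",
          as.character(utils::packageVersion("mir9step")),
          if (is.null(seed) || is.na(seed)) "NA" else seed)
}

#' Write a data frame as tab-separated text
#'
#' Values are written at 17 significant digits so trajectories
#' round-trip losslessly; a comment line names the package version and
#' the effective seed.
#'
#' @param df data frame (e.g. an `mir9_trajectory` or a co-expression
#'   summary).
#' @param path output path.
#' @param seed seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, seed = NA_integer_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(seed), con)
  fmt <- as.data.frame(lapply(df, function(x)
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)))
  names(fmt) <- names(df)
  utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv()]
#'
#' @param path input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a trajectory to TSV
#'
#' Columns `time`, `m`, `h`, `X` and (for the extended model) `Y`.
#'
#' @param traj an `mir9_trajectory`.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NA_integer_) {
  stopifnot(inherits(traj, "mir9_trajectory"))
  write_tsv(as.data.frame(traj), path, seed)
}

#' Read a trajectory TSV
#'
#' @param path input path.
#' @return An `mir9_trajectory` data frame (without model attributes).
#' @export
read_trajectory <- function(path) {
  df <- read_tsv(path)
  structure(df, class = c("mir9_trajectory", "data.frame"))
}
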