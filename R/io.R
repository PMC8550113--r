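# File formats and the command-line interface: CSV data tables, a JSON
# model description, and the fit / simulate / benchmark / dof subcommands.

# condition class used to signal user-input problems (mapped to a distinct
# CLI exit code, as opposed to non-convergence)
input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("fslmm_input_error", "error")))
}

#' Read a JSON model description
#'
#' The model file names the columns of the data table: `response` (one
#' column), `fixed_effects` (character vector), and `factors`, a list of
#' `{levels, random_effects}` entries naming each factor's level column and
#' random-effect covariate columns. Optional entries: `constraint` (see
#' Details), `contrast` (numeric vector of length `p`), and the fitting
#' options `method`, `criterion`, `tol`, `max_iter`.
#'
#' The optional `constraint` block is either
#' `{"mode": "per_factor", "structures": [...]}` with one entry per factor —
#' a builtin name (`"diagonal"`, `"compound_symmetry"`, `"identity_scaled"`,
#' `"unstructured"`) or a path to a CSV holding a dense Jacobian matrix — or
#' `{"mode": "ace", "kinship_a": [paths], "kinship_c": [paths]}` with one
#' square kinship CSV per factor (paths relative to the model file).
#'
#' @param path Path to the JSON file.
#' @return The parsed model description (list) with class `model_spec`.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) input_error("model file not found: ", path)
  spec <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) input_error("malformed JSON model file: ",
                                    conditionMessage(e)))
  for (f in c("response", "fixed_effects", "factors"))
    if (is.null(spec[[f]])) input_error("model file missing field: ", f)
  if (length(spec$factors) < 1) input_error("at least one factor is required")
  spec$dir <- dirname(path)
  class(spec) <- c("model_spec", "list")
  spec
}

# map an arbitrary level column to 1..l codes, keeping NA
encode_levels <- function(x) {
  match(x, sort(unique(x[!is.na(x)])))
}

#' Build an LMM design from a data table and model description
#'
#' @param data A data frame (e.g. read from CSV) holding all referenced
#'   columns.
#' @param spec A [read_model_spec()] result or an equivalent list.
#' @return An [lmm_design()].
#' @export
design_from_spec <- function(data, spec) {
  need <- c(spec$response, spec$fixed_effects,
            unlist(lapply(spec$factors, function(f)
              c(f$levels, f$random_effects))))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    input_error("columns not found in data: ",
                paste(missing_cols, collapse = ", "))
  Y <- as.numeric(data[[spec$response]])
  X <- as.matrix(data[spec$fixed_effects])
  if (qr(X)$rank < ncol(X))
    input_error("fixed-effects design is rank deficient")
  factors <- lapply(spec$factors, function(f)
    list(levels = encode_levels(data[[f$levels]]),
         covariates = as.matrix(data[f$random_effects])))
  tryCatch(lmm_design(Y, X, factors),
           error = function(e) input_error(conditionMessage(e)))
}

# read a constraint block into a constraint_spec (or NULL)
constraint_from_spec <- function(spec, fs) {
  cb <- spec$constraint
  if (is.null(cb)) return(NULL)
  if (identical(cb$mode, "ace")) {
    read_k <- function(p) as.matrix(utils::read.csv(
      file.path(spec$dir, p), row.names = 1, check.names = FALSE))
    return(ace_constraints(lapply(cb$kinship_a, read_k),
                           lapply(cb$kinship_c, read_k)))
  }
  if (!identical(cb$mode, "per_factor"))
    input_error("constraint mode must be 'per_factor' or 'ace'")
  if (length(cb$structures) != fs$r)
    input_error("constraint needs one structure per factor")
  entries <- lapply(seq_len(fs$r), function(k) {
    s <- cb$structures[[k]]
    if (s %in% c("diagonal", "compound_symmetry", "identity_scaled",
                 "unstructured"))
      builtin_constraints(s, fs$q[k])
    else if (file.exists(file.path(spec$dir, s)))
      linear_constraint(as.matrix(utils::read.csv(file.path(spec$dir, s))))
    else
      input_error("unknown constraint structure: ", s)
  })
  constraint_spec("per_factor", factors = entries)
}

#' Fit a model from files
#'
#' Reads a CSV data table and a JSON model description, fits the model and
#' returns a structured report. Command-line flags (method, criterion,
#' tolerance, iteration cap, contrast) override the model file's options.
#'
#' @param data_csv Path to the data CSV (header row required).
#' @param model_json Path to the JSON model description.
#' @param method,criterion,tol,max_iter Optional overrides.
#' @param contrast Optional contrast: numeric vector or comma-separated
#'   string of length-`p` weights.
#' @param verbose Print the per-iteration log-likelihood trace.
#' @return A list of class `cli_report`: estimates as labeled tables
#'   (tibbles), log-likelihood, iterations, convergence flag, warnings, and
#'   the contrast test (if requested).
#' @export
cli_fit <- function(data_csv, model_json, method = NULL, criterion = NULL,
                    tol = NULL, max_iter = NULL, contrast = NULL,
                    verbose = FALSE) {
  if (!file.exists(data_csv)) input_error("data file not found: ", data_csv)
  data <- tryCatch(utils::read.csv(data_csv, check.names = FALSE),
                   error = function(e)
                     input_error("malformed CSV: ", conditionMessage(e)))
  spec <- read_model_spec(model_json)
  design <- design_from_spec(data, spec)

  method <- toupper(method %||% spec$method %||% "FS")
  if (!method %in% c("FS", "FFS", "SFS", "FSFS", "CSFS"))
    input_error("unknown method: ", method)
  criterion <- toupper(criterion %||% spec$criterion %||% "ML")
  criterion <- c(ML = "ML", REML = "ReML")[criterion]
  if (is.na(criterion)) input_error("criterion must be ml or reml")
  control <- lmm_control(tol = as.numeric(tol %||% spec$tol %||% 1e-6),
                         max_iter = as.integer(max_iter %||%
                                                 spec$max_iter %||% 200L))
  contrast <- contrast %||% spec$contrast
  if (is.character(contrast))
    contrast <- as.numeric(strsplit(contrast, ",")[[1]])

  cspec <- constraint_from_spec(spec, design$fs)
  fit <- if (is.null(cspec))
    lmm_fit(design, method = method, criterion = criterion, control = control)
  else
    lmm_fit_constrained(design, cspec, criterion = criterion,
                        control = control)
  if (verbose)
    message(paste(sprintf("iter %d: loglik %.8f",
                          seq_along(fit$loglik_trace) - 1L,
                          fit$loglik_trace), collapse = "\n"))

  report <- list(
    method = fit$method, criterion = fit$criterion,
    beta = tibble::tibble(term = spec$fixed_effects, estimate = fit$beta),
    sigma2 = fit$sigma2,
    D = lapply(seq_along(fit$D), function(k) {
      Dk <- fit$sigma2 * fit$D[[k]]
      dimnames(Dk) <- list(spec$factors[[k]]$random_effects,
                           spec$factors[[k]]$random_effects)
      Dk
    }),
    loglik = fit$loglik, n_iter = fit$n_iter, converged = fit$converged,
    warnings = fit$warnings)
  if (!is.null(contrast)) {
    if (length(contrast) != ncol(design$X))
      input_error("contrast must have ", ncol(design$X), " weights")
    report$contrast <- approx_t(fit, contrast)
  }
  class(report) <- c("cli_report", "list")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cli_report <- function(x, ...) {
  cat(sprintf("Model fit (%s, %s): %s after %d iterations\n",
              x$method, x$criterion,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("log-likelihood: %.6f   sigma2: %.6f\n", x$loglik, x$sigma2))
  cat("fixed effects:\n"); print(x$beta)
  for (k in seq_along(x$D)) {
    cat(sprintf("random-effect covariance (sigma2 * D), factor %d:\n", k))
    print(round(x$D[[k]], 6))
  }
  if (!is.null(x$contrast)) {
    cat("contrast test:\n"); print(x$contrast)
  }
  if (length(x$warnings))
    cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# serialise a cli_report (or any benchmark output) to JSON
write_report_json <- function(report, path) {
  out <- report
  class(out) <- "list"
  out$D <- lapply(out$D, function(Dk) unclass(as.data.frame(Dk)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# flat data table of a simulated dataset: y, x1..xp, then per factor the
# level column and raw covariate columns
dataset_to_table <- function(ds) {
  d <- ds$design
  X <- d$X
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- data.frame(y = d$Y, X, check.names = FALSE)
  for (k in seq_len(d$fs$r)) {
    out[[paste0("f", k, "_level")]] <- d$fs$level_of[[k]]
    cm <- d$covariates[[k]]
    for (e in seq_len(ncol(cm)))
      out[[paste0("f", k, "_z", e)]] <- cm[, e]
  }
  out
}

# model spec matching dataset_to_table's column names
dataset_model_spec <- function(ds) {
  d <- ds$design
  list(response = "y",
       fixed_effects = paste0("x", seq_len(ncol(d$X))),
       factors = lapply(seq_len(d$fs$r), function(k)
         list(levels = paste0("f", k, "_level"),
              random_effects = paste0("f", k, "_z",
                                      seq_len(d$fs$q[k])))))
}

#' Simulate datasets to files
#'
#' Writes `reps` simulated datasets (`data_<i>.csv`), one shared
#' `model.json` naming their columns, and `truth.json` with the generating
#' parameters. Deterministic given `seed`; each replicate uses a child seed
#' expanded from it.
#'
#' @param setting A [sim_setting()] or a preset name.
#' @param seed Parent seed.
#' @param reps Number of datasets.
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
cli_simulate <- function(setting, seed = 1, reps = 1, out_dir = ".") {
  if (is.character(setting)) setting <- sim_setting(setting)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, reps)
  spec_written <- FALSE
  for (i in seq_len(reps)) {
    ds <- generate_dataset(setting, seed = child[i])
    utils::write.csv(dataset_to_table(ds),
                     file.path(out_dir, sprintf("data_%d.csv", i)),
                     row.names = FALSE)
    if (!spec_written) {
      jsonlite::write_json(dataset_model_spec(ds),
                           file.path(out_dir, "model.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      spec_written <- TRUE
    }
  }
  jsonlite::write_json(
    list(beta = setting$beta, sigma2 = setting$sigma2,
         D = lapply(setting$D, function(M) unclass(as.data.frame(M))),
         seed = seed, n = setting$n, q = setting$q, l = setting$l),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' Run an estimation benchmark and write its reports
#'
#' @inheritParams estimation_benchmark
#' @param out_prefix Path prefix; writes `<prefix>_replicates.csv`,
#'   `<prefix>_summary.csv` and `<prefix>.json`.
#' @return The [estimation_benchmark()] report, invisibly.
#' @export
cli_benchmark <- function(setting, methods = c("FS", "FFS", "SFS", "FSFS"),
                          criterion = "ML", n_reps = 20, seed = 1,
                          out_prefix = "benchmark") {
  if (is.character(setting)) setting <- sim_setting(setting)
  rep_dir <- dirname(out_prefix)
  if (nzchar(rep_dir)) dir.create(rep_dir, recursive = TRUE,
                                  showWarnings = FALSE)
  bm <- estimation_benchmark(setting, methods = methods,
                             criterion = criterion, n_reps = n_reps,
                             seed = seed)
  utils::write.csv(bm$replicates, paste0(out_prefix, "_replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(bm$summary, paste0(out_prefix, "_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(setting = setting$name, criterion = criterion, seed = seed,
         n_reps = n_reps, summary = bm$summary),
    paste0(out_prefix, ".json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(bm)
}

#' Run the degrees-of-freedom harness and write its report
#'
#' @inheritParams dof_benchmark
#' @param out Output JSON path.
#' @return The [dof_benchmark()] result, invisibly.
#' @export
cli_dof <- function(setting, n_reps = 100, n_truth_reps = n_reps, seed = 1,
                    out = "dof.json") {
  if (is.character(setting)) setting <- sim_setting(setting)
  res <- dof_benchmark(setting, n_reps = n_reps,
                       n_truth_reps = n_truth_reps, seed = seed)
  jsonlite::write_json(
    res[c("mean_dof", "sd_dof", "truth_dof", "n_dropped", "contrast")],
    out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

# --key value / --flag argument parser; boolean switches never consume the
# following token
parse_flags <- function(args, switches = "verbose") {
  flags <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (key %in% switches) {
        flags[[key]] <- TRUE; i <- i + 1L
      } else if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        flags[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        flags[[key]] <- TRUE; i <- i + 1L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(flags = flags, positional = pos)
}

cli_usage <- function() {
  paste(
    "usage: fslmm <subcommand> [options]",
    "  fit <data.csv> <model.json> [--method fs|ffs|sfs|fsfs|csfs]",
    "      [--criterion ml|reml] [--tol T] [--max-iter N]",
    "      [--contrast w1,w2,...] [--out report.json] [--verbose]",
    "  simulate --setting setting1|setting2|setting3 [--seed S] [--reps R]",
    "      [--out-dir DIR]",
    "  benchmark --setting NAME [--methods fs,ffs,...] [--criterion ml|reml]",
    "      [--reps R] [--seed S] [--out-prefix PREFIX]",
    "  dof --setting NAME [--reps R] [--truth-reps R2] [--seed S] [--out F]",
    sep = "\n")
}

#' Command-line entry point
#'
#' Dispatches the `fit`, `simulate`, `benchmark` and `dof` subcommands and
#' returns the process exit code: 0 on success (and convergence, for
#' `fit`), 2 on input errors, 3 when a fit did not converge, 64 on usage
#' errors.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) { message(cli_usage()); return(invisible(64L)) }
  sub <- args[1]
  pa <- parse_flags(args[-1])
  fl <- pa$flags
  code <- tryCatch({
    switch(sub,
      fit = {
        if (length(pa$positional) < 2) { message(cli_usage()); return(invisible(64L)) }
        rep <- cli_fit(pa$positional[1], pa$positional[2],
                       method = fl$method, criterion = fl$criterion,
                       tol = fl$tol, max_iter = fl$max_iter,
                       contrast = fl$contrast,
                       verbose = isTRUE(fl$verbose))
        print(rep)
        if (!is.null(fl$out)) write_report_json(rep, fl$out)
        if (rep$converged) 0L else 3L
      },
      simulate = {
        if (is.null(fl$setting)) { message(cli_usage()); return(invisible(64L)) }
        cli_simulate(fl$setting, seed = as.integer(fl$seed %||% 1),
                     reps = as.integer(fl$reps %||% 1),
                     out_dir = fl$out_dir %||% ".")
        0L
      },
      benchmark = {
        if (is.null(fl$setting)) { message(cli_usage()); return(invisible(64L)) }
        methods <- toupper(strsplit(fl$methods %||% "fs,ffs,sfs,fsfs",
                                    ",")[[1]])
        bm <- cli_benchmark(fl$setting, methods = methods,
                            criterion = c(ML = "ML", REML = "ReML")[
                              toupper(fl$criterion %||% "ml")],
                            n_reps = as.integer(fl$reps %||% 20),
                            seed = as.integer(fl$seed %||% 1),
                            out_prefix = fl$out_prefix %||% "benchmark")
        print(bm)
        0L
      },
      dof = {
        if (is.null(fl$setting)) { message(cli_usage()); return(invisible(64L)) }
        n_reps <- as.integer(fl$reps %||% 100)
        res <- cli_dof(fl$setting, n_reps = n_reps,
                       n_truth_reps = as.integer(fl$truth_reps %||% n_reps),
                       seed = as.integer(fl$seed %||% 1),
                       out = fl$out %||% "dof.json")
        message(sprintf("mean dof %.3f (sd %.3f), harness truth %.3f",
                        res$mean_dof, res$sd_dof, res$truth_dof))
        0L
      },
      { message(cli_usage()); 64L })
  },
  fslmm_input_error = function(e) { message("input error: ",
                                            conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(code)
}
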