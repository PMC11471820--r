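# Delimited-text trace files and structured configs.
#
# One tab-separated file per probe energy with header columns
# delay_ps, dA, sigma and a `# probe_energy_eV:` comment line; plain text
# so scans diff cleanly under version control.

#' Write transient traces to delimited text files
#'
#' @param traces Tidy trace tibble (`probe_energy`, `delay_ps`, `dA`,
#'   `sigma`).
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix; files are named
#'   `<prefix>_<energy>eV.tsv`.
#' @return Invisibly, the written file paths.
#' @export
write_traces <- function(traces, dir, prefix = "trace") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  energies <- unique(traces$probe_energy)
  paths <- character(0)
  for (en in energies) {
    df <- traces[traces$probe_energy == en, c("delay_ps", "dA", "sigma")]
    path <- file.path(dir, sprintf("%s_%.1feV.tsv", prefix, en))
    con <- file(path, "w")
    writeLines(sprintf("# probe_energy_eV: %.4f", en), con)
    close(con)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read transient traces from delimited text files
#'
#' Parses and validates delay-scan files written by [write_traces()] (or
#' hand-made files with the same layout): header columns `delay_ps`, `dA`,
#' `sigma`, optional `# probe_energy_eV:` comment. Malformed rows,
#' non-monotonic delays and non-positive uncertainties are rejected with
#' the offending file and line named.
#'
#' @param paths Character vector of file paths.
#' @return Tidy tibble `probe_energy`, `delay_ps`, `dA`, `sigma` (class
#'   `transient_traces`).
#' @export
read_traces <- function(paths) {
  out <- purrr::map_dfr(paths, function(path) {
    if (!file.exists(path)) abort(sprintf("trace file not found: %s", path))
    lines <- readLines(path)
    energy <- NA_real_
    m <- grep("^#\\s*probe_energy_eV:", lines, value = TRUE)
    if (length(m)) {
      energy <- as.numeric(sub("^#\\s*probe_energy_eV:\\s*", "", m[1]))
    } else {
      g <- regmatches(basename(path),
                      regexpr("[0-9]+(\\.[0-9]+)?(?=eV)", basename(path),
                              perl = TRUE))
      if (length(g)) energy <- as.numeric(g)
    }
    if (is.na(energy)) {
      abort(sprintf("%s: probe energy not found in header comment or filename.",
                    path))
    }
    hdr_at <- which(!startsWith(lines, "#"))[1]
    hdr <- strsplit(lines[hdr_at], "\t")[[1]]
    if (!all(c("delay_ps", "dA", "sigma") %in% hdr)) {
      abort(sprintf("%s: header must contain delay_ps, dA, sigma.", path))
    }
    body <- lines[-seq_len(hdr_at)]
    body <- body[!startsWith(body, "#") & nzchar(body)]
    rows <- strsplit(body, "\t")
    n_col <- length(hdr)
    for (i in seq_along(rows)) {
      ln_no <- hdr_at + i
      if (length(rows[[i]]) != n_col) {
        abort(sprintf("%s line %d: expected %d fields, found %d.",
                      path, ln_no, n_col, length(rows[[i]])))
      }
      vals <- suppressWarnings(as.numeric(rows[[i]]))
      if (any(is.na(vals))) {
        abort(sprintf("%s line %d: non-numeric value.", path, ln_no))
      }
    }
    df <- as_tibble(setNames(as.data.frame(
      matrix(as.numeric(unlist(rows)), ncol = n_col, byrow = TRUE)), hdr))
    df <- df[, c("delay_ps", "dA", "sigma")]
    bad_sigma <- which(df$sigma <= 0)
    if (length(bad_sigma)) {
      abort(sprintf("%s line %d: sigma must be > 0.",
                    path, hdr_at + bad_sigma[1]))
    }
    if (is.unsorted(df$delay_ps, strictly = TRUE)) {
      abort(sprintf("%s: delays must be strictly increasing.", path))
    }
    tibble(probe_energy = energy, delay_ps = df$delay_ps,
           dA = df$dA, sigma = df$sigma)
  })
  class(out) <- c("transient_traces", class(out))
  out
}

# configs -------------------------------------------------------------------

.config_keys <- c("tau1", "q21", "tau21", "q22", "tau22", "tau23",
                  "q31", "tau31", "tau32", "q41", "tau41", "tau42",
                  "sigma_irf", "t0")

#' Write kinetic parameters and IRF to a YAML config
#'
#' Keys follow the scheme's symbols (`tau1`, `q21`, `tau21`, ...,
#' `sigma_irf`, `t0`); infinite time constants are written as the string
#' `.inf`.
#'
#' @param params A [kinetic_parameters] object.
#' @param irf An [irf_model].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_params_config <- function(params, irf, path) {
  vals <- unclass(params)[setdiff(.config_keys, c("sigma_irf", "t0"))]
  vals$sigma_irf <- irf$sigma
  vals$t0 <- irf$t0
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Read kinetic parameters and IRF from a YAML config
#'
#' Unknown keys are rejected: a config that does not validate against the
#' scheme never reaches any computation.
#'
#' @param path Config path.
#' @return `list(params = kinetic_parameters, irf = irf_model)`.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown)) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  missing_q <- setdiff(c("tau1", "q21", "tau21", "q22", "tau22",
                         "q31", "tau31", "tau32", "q41", "tau41"),
                       names(raw))
  if (length(missing_q)) {
    abort(sprintf("config missing keys: %s", paste(missing_q, collapse = ", ")))
  }
  num <- function(x) if (is.character(x) && grepl("inf", x, ignore.case = TRUE))
    Inf else as.numeric(x)
  params <- kinetic_parameters(
    tau1 = num(raw$tau1),
    q21 = num(raw$q21), tau21 = num(raw$tau21),
    q22 = num(raw$q22), tau22 = num(raw$tau22),
    tau23 = if (is.null(raw$tau23)) Inf else num(raw$tau23),
    q31 = num(raw$q31), tau31 = num(raw$tau31),
    tau32 = num(raw$tau32),
    q41 = num(raw$q41), tau41 = num(raw$tau41),
    tau42 = if (is.null(raw$tau42)) Inf else num(raw$tau42)
  )
  irf <- irf_model(sigma = if (is.null(raw$sigma_irf)) 0.087 else num(raw$sigma_irf),
                   t0 = if (is.null(raw$t0)) 0 else num(raw$t0))
  list(params = params, irf = irf)
}

# reporting -----------------------------------------------------------------

#' Structured report of a global fit
#'
#' Collects the parameter estimates and uncertainties, goodness of fit,
#' and the derived headline quantities of the recombination scheme (the
#' 20-ps thiyl recombined fraction, the ground-state recovery at 1 ns and
#' asymptotically) into a machine-readable list; optionally written as
#' JSON. A `NULL` or failed fit gives a stub report with `failed = TRUE`
#' rather than an error.
#'
#' @param fit A `cystine_fit`, or `NULL`.
#' @param path Optional JSON output path.
#' @return The report list, invisibly if `path` is given.
#' @export
fit_report <- function(fit, path = NULL) {
  if (is.null(fit)) {
    rep <- list(failed = TRUE, reason = "no fit result")
  } else {
    pt <- fit$spec$par_table
    n0_1ns <- solve_populations(fit$params, 1000)$N0
    rep <- list(
      failed = FALSE,
      converged = fit$converged,
      message = trimws(fit$message),
      reduced_chi2 = fit$reduced_chi2,
      n_obs = fit$n_obs,
      n_free = fit$n_free,
      parameters = lapply(setNames(pt$name, pt$name), function(nm) {
        list(estimate = unname(fit$estimates[[nm]]),
             std_error = unname(fit$se[[nm]]),
             fixed = !pt$vary[pt$name == nm])
      }),
      derived = list(
        recombined_fraction_20ps = recombined_fraction(fit$params, 20),
        recovery_1ns = n0_1ns,
        recovery_asymptotic = asymptotic_recovery(fit$params)
      )
    )
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
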