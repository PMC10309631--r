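# Named scenario registry, flat key-value configs, and run orchestration.

#' Construct a scenario
#'
#' A scenario bundles everything one run needs: a parameterization, an
#' initial state, optionally a control block (post-intervention parameters
#' plus an endangerment threshold), optionally a one-parameter sweep, the
#' products to produce, and a provenance note.
#'
#' @param name scenario name.
#' @param params a [model_params()] object.
#' @param x0 initial proportions, length 2 or 3 (renormalized at run time
#'   if needed).
#' @param control `NULL`, or `list(params = <model_params>, ET = <threshold>)`.
#' @param sweep `NULL`, or `list(parameter = <name>, values = <numeric>,
#'   complement = <name or NULL>)`; with a complement set, the complement
#'   parameter is kept at `1 - value` (used for complementary statuses).
#' @param outputs character subset of
#'   `c("equilibria", "simulate", "sliding", "portrait")`.
#' @param notes free-text provenance string.
#' @return An object of class `"ling_scenario"`.
#' @export
scenario <- function(name, params, x0 = c(0.33, 0.33, 0.34), control = NULL,
                     sweep = NULL, outputs = "simulate", notes = "") {
  stopifnot(inherits(params, "model_params"),
            all(outputs %in% c("equilibria", "simulate", "sliding", "portrait")))
  x0 <- suppressWarnings(.as_state(x0))
  if (!is.null(control)) {
    stopifnot(is.list(control), inherits(control$params, "model_params"),
              is.numeric(control$ET), control$ET > 0, control$ET < 1)
  }
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep), sweep$parameter %in% names(unclass(params)),
              is.numeric(sweep$values), length(sweep$values) >= 2)
  }
  structure(list(name = name, params = params, x0 = x0, control = control,
                 sweep = sweep, outputs = outputs, notes = notes),
            class = "ling_scenario")
}

#' @export
print.ling_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (outputs: %s)\n", x$name,
              paste(x$outputs, collapse = ", ")))
  print(x$params)
  cat(sprintf("  x0 = (%.4f, %.4f, %.4f)\n", x$x0[1], x$x0[2], x$x0[3]))
  if (!is.null(x$control)) {
    cat(sprintf("  control below ET = %g:\n", x$control$ET))
    print(x$control$params)
  }
  if (!is.null(x$sweep)) {
    cat(sprintf("  sweep: %s in {%s}\n", x$sweep$parameter,
                paste(x$sweep$values, collapse = ", ")))
  }
  if (nzchar(x$notes)) cat("  notes:", x$notes, "\n")
  invisible(x)
}

# Built-in scenarios. mu = 0.02 throughout; a = 1.31 for the time-series
# examples, a = 1 for the control-policy studies. The free/controlled
# parameter tables of the policy scenarios share mu and a.
.registry <- function() {
  tbl1 <- model_params(0.02, 1.31, 0.4, 0.6, I_wA = 10)
  tbl2 <- model_params(0.02, 1.31, 0.6, 0.4, I_wA = 10)
  tbl3 <- model_params(0.02, 1.00, 0.8, 0.2, I_Aw = 0.03, I_Bw = 0.03)
  tbl4 <- model_params(0.02, 1.00, 0.6, 0.4, I_Aw = 0.03, I_Bw = 0.03)
  tbl5 <- model_params(0.02, 1.00, 0.8, 0.2, I_Aw = 0.06, I_Bw = 0.06)
  tbl6 <- model_params(0.02, 1.00, 0.6, 0.4, I_Aw = 0.06, I_Bw = 0.06)
  x0 <- c(0.33, 0.33, 0.34)
  list(
    example1 = scenario(
      "example1", tbl1, x0, outputs = c("simulate", "equilibria"),
      notes = paste("High bilingual-to-A interaction (I_wA = 10), B higher",
                    "status. NOTE: announced in its original account as",
                    "converging to E1(0,1,0); integrating the stated",
                    "equations yields E2(1,0,0) - flagged discrepancy.")),
    example2 = scenario(
      "example2", tbl2, x0, outputs = c("simulate", "equilibria"),
      notes = "Statuses swapped relative to example1; A prevails (E2)."),
    example2_high_status = scenario(
      "example2_high_status",
      model_params(0.02, 1.31, 0.9, 0.1, I_wA = 10), x0,
      outputs = "simulate",
      notes = "Raising s_A to 0.9 accelerates the extinction of B."),
    example3_sweep = scenario(
      "example3_sweep", model_params(0.02, 1.31, 0.5, 0.5, I_wA = 10),
      c(0.33, 0.33, 0.33),
      sweep = list(parameter = "s_A", values = c(0.1, 0.3, 0.5, 0.7, 0.95),
                   complement = "s_B"),
      outputs = "simulate",
      notes = paste("Status sweep with s_B = 1 - s_A; initial proportions",
                    "sum to 0.99 and are renormalized. NOTE: for s_A in",
                    "{0.1, 0.3} the dynamics of the stated equations make",
                    "B prevail, so no B-extinction time exists there -",
                    "flagged discrepancy with the announced summary.")),
    example4_sweep = scenario(
      "example4_sweep", model_params(0.02, 1.31, 0.6, 0.4, I_wA = 10), x0,
      sweep = list(parameter = "I_wA", values = c(1, 5, 10, 30),
                   complement = NULL),
      outputs = "simulate",
      notes = "Bilingual-to-A interaction sweep; B extinction accelerates."),
    example5 = scenario(
      "example5", tbl1, c(0.3, 0.5, 0.2), outputs = "simulate",
      notes = paste("Heterogeneous initial distribution; reaches E1(0,1,0)",
                    "faster than example1 reaches its attractor. Its",
                    "original prose ('only speak language A') contradicts",
                    "its own E1 label; the dynamics yield E1.")),
    fig8a = scenario(
      "fig8a", tbl3, x0, outputs = c("equilibria", "portrait"),
      notes = "Uncontrolled baseline policy study (a = 1)."),
    fig8b = scenario(
      "fig8b", tbl3, x0, control = list(params = tbl4, ET = 0.3),
      outputs = c("sliding", "portrait"),
      notes = "Status-only intervention: sliding segment, no pseudo-equilibrium."),
    fig8c = scenario(
      "fig8c", tbl3, x0, control = list(params = tbl5, ET = 0.3),
      outputs = c("sliding", "portrait"),
      notes = "Interaction-only intervention: no sliding segment."),
    fig8d = scenario(
      "fig8d", tbl3, x0, control = list(params = tbl6, ET = 0.3),
      outputs = c("sliding", "portrait"),
      notes = "Combined intervention: pseudo-equilibrium (coexistence).")
  )
}

#' List the built-in scenarios
#' @return Character vector of registered scenario names.
#' @export
list_scenarios <- function() names(.registry())

#' Load a scenario by name or from a config file
#'
#' @param name_or_path a registered scenario name (see [list_scenarios()])
#'   or the path of a flat key-value config file (see
#'   [read_scenario_config()]).
#' @return A `"ling_scenario"`.
#' @export
load_scenario <- function(name_or_path) {
  reg <- .registry()
  if (name_or_path %in% names(reg)) return(reg[[name_or_path]])
  if (file.exists(name_or_path)) return(read_scenario_config(name_or_path))
  stop("unknown scenario '", name_or_path, "'; registered: ",
       paste(names(reg), collapse = ", "))
}

.param_keys <- c("mu", "a", "s_A", "s_B", "I_wA", "I_wB", "I_Aw", "I_Bw")

#' Write a scenario to a flat key-value config file
#'
#' The format is one `key = value` pair per line, `#` comments. Model
#' parameters use their plain names, control-regime parameters the `ctrl_`
#' prefix, the threshold the key `ET`, the initial state `x_A0`, `x_B0`,
#' `w0`.
#'
#' @param s a `"ling_scenario"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(s, path) {
  stopifnot(inherits(s, "ling_scenario"))
  p <- unclass(s$params)
  lines <- c(sprintf("# lingslide scenario config"),
             sprintf("name = %s", s$name),
             sprintf("%s = %.17g", .param_keys, unlist(p[.param_keys])),
             sprintf("x_A0 = %.17g", s$x0[1]),
             sprintf("x_B0 = %.17g", s$x0[2]),
             sprintf("w0 = %.17g", s$x0[3]))
  if (!is.null(s$control)) {
    cp <- unclass(s$control$params)
    lines <- c(lines,
               sprintf("ctrl_%s = %.17g", .param_keys, unlist(cp[.param_keys])),
               sprintf("ET = %.17g", s$control$ET))
  }
  if (!is.null(s$sweep)) {
    lines <- c(lines,
               sprintf("sweep_parameter = %s", s$sweep$parameter),
               sprintf("sweep_values = %s",
                       paste(sprintf("%.17g", s$sweep$values), collapse = ",")),
               if (!is.null(s$sweep$complement))
                 sprintf("sweep_complement = %s", s$sweep$complement))
  }
  lines <- c(lines,
             sprintf("outputs = %s", paste(s$outputs, collapse = ",")),
             sprintf("notes = %s", gsub("\n", " ", s$notes)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scenario from a flat key-value config file
#'
#' @param path config file path (format of [write_scenario_config()]).
#' @return A `"ling_scenario"`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  m <- regmatches(raw, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", raw))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("malformed config line: ", raw[bad][1])
  kv <- setNames(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 2L))
  need <- function(k) {
    if (!k %in% names(kv)) stop("config is missing required key '", k, "'")
    kv[[k]]
  }
  num <- function(k) {
    v <- suppressWarnings(as.numeric(need(k)))
    if (is.na(v)) stop("config key '", k, "' is not numeric: ", kv[[k]])
    v
  }
  params <- do.call(model_params, setNames(lapply(.param_keys, num), .param_keys))
  x0 <- c(num("x_A0"), num("x_B0"), num("w0"))
  control <- NULL
  if ("ET" %in% names(kv)) {
    ck <- paste0("ctrl_", .param_keys)
    cp <- do.call(model_params, setNames(lapply(ck, num), .param_keys))
    control <- list(params = cp, ET = num("ET"))
  }
  sweep <- NULL
  if ("sweep_parameter" %in% names(kv)) {
    sweep <- list(parameter = need("sweep_parameter"),
                  values = as.numeric(strsplit(need("sweep_values"), ",")[[1]]),
                  complement = if ("sweep_complement" %in% names(kv))
                    kv[["sweep_complement"]] else NULL)
  }
  outputs <- strsplit(need("outputs"), ",")[[1]]
  scenario(name = if ("name" %in% names(kv)) kv[["name"]] else basename(path),
           params = params, x0 = x0, control = control, sweep = sweep,
           outputs = outputs,
           notes = if ("notes" %in% names(kv)) kv[["notes"]] else "")
}

# Provenance header echoed into every output file.
.provenance <- function(s, seed = NULL) {
  p <- unclass(s$params)
  lines <- c(sprintf("# scenario: %s", s$name),
             sprintf("# %s: %g", .param_keys, unlist(p[.param_keys])),
             sprintf("# x0: %g %g %g", s$x0[1], s$x0[2], s$x0[3]))
  if (!is.null(s$control)) {
    cp <- unclass(s$control$params)
    lines <- c(lines,
               sprintf("# ctrl_%s: %g", .param_keys, unlist(cp[.param_keys])),
               sprintf("# ET: %g", s$control$ET))
  }
  c(lines,
    if (!is.null(seed)) sprintf("# seed: %d", seed),
    sprintf("# lingslide version: %s",
            as.character(utils::packageVersion("lingslide"))))
}

.write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a scenario and collect (optionally write) its products
#'
#' Dispatches to the analysis modules. With `out_dir` set, time series and
#' grids are written as CSV and reports as JSON, each carrying a provenance
#' header (full parameter echo).
#'
#' @param s a `"ling_scenario"` (or a name/path accepted by
#'   [load_scenario()]).
#' @param what which product to compute; defaults to the scenario's first
#'   registered output.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param t_max integration horizon for trajectory products.
#' @param seed integer echoed into provenance headers (the analyses here
#'   are deterministic; the seed is recorded for reproducibility of any
#'   downstream stochastic use).
#' @return Invisibly, a list with `scenario`, `what`, `summary` (plain
#'   list), `result` (the full module object) and `files` (paths written).
#' @export
run_scenario <- function(s, what = NULL, out_dir = NULL, t_max = 2000,
                         seed = NULL) {
  if (is.character(s)) s <- load_scenario(s)
  stopifnot(inherits(s, "ling_scenario"))
  if (is.null(what)) what <- s$outputs[1]
  what <- match.arg(what, c("equilibria", "simulate", "sliding", "portrait"))
  coeffs <- reduced_coefficients(s$params)
  a <- s$params$a
  header <- .provenance(s, seed)
  files <- character(0)
  emit_csv <- function(df, stem) {
    if (is.null(out_dir)) return()
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    f <- file.path(out_dir, paste0(s$name, "_", stem, ".csv"))
    .write_csv_with_header(df, f, header)
    files <<- c(files, f)
  }
  emit_json <- function(obj, stem) {
    if (is.null(out_dir)) return()
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    f <- file.path(out_dir, paste0(s$name, "_", stem, ".json"))
    obj$provenance <- sub("^# ", "", header)
    jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA, null = "null")
    files <<- c(files, f)
  }

  if (what == "equilibria") {
    pts <- trivial_equilibria()
    reports <- lapply(rownames(pts), function(nm)
      classify_equilibrium(coeffs, a, pts[nm, ]))
    names(reports) <- rownames(pts)
    e3 <- tryCatch(interior_equilibrium(coeffs, a), error = function(e) NULL)
    if (!is.null(e3)) reports$E3 <- classify_equilibrium(coeffs, a, e3)
    summary <- lapply(reports, function(r)
      list(point = round(unname(r$point), 4), p = r$p, q = r$q,
           classification = r$classification))
    emit_json(list(equilibria = summary), "equilibria")
    result <- reports
  } else if (what == "simulate") {
    if (!is.null(s$sweep)) {
      vals <- s$sweep$values
      rows <- lapply(vals, function(v) {
        p <- unclass(s$params)
        p[[s$sweep$parameter]] <- v
        if (!is.null(s$sweep$complement)) p[[s$sweep$complement]] <- 1 - v
        pm <- do.call(model_params, p[.param_keys])
        tr <- integrate_smooth(reduced_coefficients(pm), pm$a, s$x0,
                               t_max = t_max)
        data.frame(value = v,
                   fpt_x_B = first_passage_time(tr, "x_B"),
                   fpt_x_A = first_passage_time(tr, "x_A"),
                   final_x_A = tr$final_state[["x_A"]],
                   final_x_B = tr$final_state[["x_B"]])
      })
      result <- do.call(rbind, rows)
      result <- cbind(parameter = s$sweep$parameter, result)
      emit_csv(result, "sweep")
      summary <- list(sweep = s$sweep$parameter, table = result)
    } else {
      tr <- integrate_smooth(coeffs, a, s$x0, t_max = t_max)
      att <- attractor_of(coeffs, a, s$x0)
      emit_csv(tr$data, "trajectory")
      summary <- list(final_state = unname(round(att$state, 6)),
                      matched_equilibrium = att$label,
                      converged = att$converged)
      emit_json(summary, "summary")
      result <- list(trajectory = tr, attractor = att)
    }
  } else if (what == "sliding") {
    if (is.null(s$control)) stop("scenario '", s$name, "' has no control block")
    fm <- filippov_model(coeffs, reduced_coefficients(s$control$params),
                         a = a, ET = s$control$ET)
    an <- pseudo_equilibrium(fm)
    tr <- integrate_hybrid(fm, s$x0, t_max = t_max)
    emit_csv(tr$data, "trajectory")
    summary <- list(
      sliding_segments = if (nrow(an$segments)) round(unclass(an$segments), 6),
      pseudo_equilibrium = if (!is.null(an$pseudo_equilibrium))
        unname(round(an$pseudo_equilibrium, 4)),
      pseudo_equilibrium_display = if (!is.null(an$pseudo_equilibrium))
        unname(round(an$pseudo_equilibrium, 2)),
      lambda = an$lambda_at_pe,
      final_state = unname(round(tr$final_state, 6)),
      converged = tr$converged)
    emit_json(summary, "sliding")
    result <- list(analysis = an, trajectory = tr)
  } else { # portrait
    model <- if (!is.null(s$control)) {
      filippov_model(coeffs, reduced_coefficients(s$control$params),
                     a = a, ET = s$control$ET)
    } else coeffs
    nc <- nullclines(coeffs, a)
    grid <- vector_field_grid(model, a = a)
    emit_csv(nc, "nullclines")
    emit_csv(grid, "grid")
    summary <- list(n_nullcline_vertices = nrow(nc), n_grid = nrow(grid))
    result <- list(nullclines = nc, grid = grid)
  }
  invisible(list(scenario = s$name, what = what, summary = summary,
                 result = result, files = files))
}
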