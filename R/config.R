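#' Parse a run configuration file
#'
#' Reads a YAML run configuration describing 1-4 particle models (each a
#' list of subunits plus per-model polydispersity, structure factor and
#' experiment settings), a shared q grid and a seed, validates it, and
#' fills in documented defaults for every omitted field. Unknown keys are
#' rejected to catch typos, and dimension-count errors name the offending
#' subunit.
#'
#' Defaults: `n_points = 3000`, `n_bins = 200`, q grid 400 log-spaced
#' points in `[1e-3, 0.5]` 1/A (keys `min`, `max`, `n_q`, `spacing`;
#' the count key is `n_q` because YAML parses a bare `n` as a boolean),
#' `sigma_s = 0`, no structure factor,
#' `sigma_rough = 0`, `eta = 0.01`, `exposure = 1`, `seed = 1`,
#' `exclude_overlap = TRUE`, `output_dir = "."`, `plot = FALSE`.
#'
#' @param path Path to a YAML file, or a list already parsed from one.
#' @return A validated `run_config` list.
#' @seealso [run_models()] for executing a configuration; the README shows
#'   a complete example file.
#' @export
parse_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  .check_keys(cfg, c("models", "q_grid", "seed", "output_dir", "plot"),
              "top level")
  if (is.null(cfg$models) || !length(cfg$models)) {
    stop("config error: 'models' must list at least one model", call. = FALSE)
  }
  if (length(cfg$models) > 4) {
    stop("config error: at most four models per run", call. = FALSE)
  }
  qg <- cfg$q_grid %||% list()
  # note: the count key is 'n_q', not 'n' -- YAML 1.1 parses a bare 'n'
  # key as the boolean FALSE
  .check_keys(qg, c("min", "max", "n_q", "spacing"), "q_grid")
  q_grid <- list(min = qg$min %||% 1e-3, max = qg$max %||% 0.5,
                 n_q = qg$n_q %||% 400, spacing = qg$spacing %||% "log")
  if (q_grid$min <= 0 || q_grid$max <= q_grid$min) {
    stop("config error: q_grid must satisfy 0 < min < max", call. = FALSE)
  }
  models <- lapply(seq_along(cfg$models), function(i) {
    .parse_model(cfg$models[[i]], i)
  })
  nm <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("config error: model names must be unique", call. = FALSE)
  }
  structure(list(models = models, q_grid = q_grid,
                 seed = as.integer(cfg$seed %||% 1L),
                 output_dir = cfg$output_dir %||% ".",
                 plot = isTRUE(cfg$plot)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("config error: unknown key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

.parse_model <- function(m, i) {
  .check_keys(m, c("name", "subunits", "n_points", "n_bins",
                   "exclude_overlap", "sigma_s", "structure_factor",
                   "experiment"), sprintf("model %d", i))
  if (is.null(m$subunits) || !length(m$subunits)) {
    stop(sprintf("config error: model %d has no subunits", i), call. = FALSE)
  }
  subunits <- lapply(seq_along(m$subunits), function(j) {
    s <- m$subunits[[j]]
    .check_keys(s, c("kind", "dims", "delta_sld", "com"),
                sprintf("model %d subunit %d", i, j))
    if (is.null(s$kind)) {
      stop(sprintf("config error: model %d subunit %d has no kind", i, j),
           call. = FALSE)
    }
    tryCatch(
      subunit(s$kind, unlist(s$dims), s$delta_sld %||% 1,
              unlist(s$com %||% c(0, 0, 0))),
      error = function(e) {
        stop(sprintf("config error in model %d subunit %d ('%s'): %s",
                     i, j, s$kind, conditionMessage(e)), call. = FALSE)
      })
  })
  ex <- m$experiment %||% list()
  .check_keys(ex, c("eta", "exposure", "sigma_rough", "noise_scale",
                    "noise_c", "noise_k"), sprintf("model %d experiment", i))
  params <- experiment_params(
    eta = ex$eta %||% 0.01, exposure = ex$exposure %||% 1,
    sigma_rough = ex$sigma_rough %||% 0,
    noise_scale = ex$noise_scale %||% 1,
    noise_c = ex$noise_c %||% 0.85, noise_k = ex$noise_k %||% 4500)
  sf <- m$structure_factor
  if (!is.null(sf)) {
    if (identical(sf$type, "hard_sphere")) {
      .check_keys(sf, c("type", "r_hs", "eta"),
                  sprintf("model %d structure_factor", i))
      sf <- list(type = "hard_sphere", r_hs = sf$r_hs %||% 50,
                 eta = sf$eta %||% 0.1)
    } else if (identical(sf$type, "fractal")) {
      .check_keys(sf, c("type", "frac", "n_agg", "r_eff"),
                  sprintf("model %d structure_factor", i))
      sf <- list(type = "fractal", frac = sf$frac %||% 1,
                 n_agg = sf$n_agg %||% 10, r_eff = sf$r_eff %||% 50)
    } else {
      stop(sprintf(
        "config error: model %d structure_factor type must be 'hard_sphere' or 'fractal'",
        i), call. = FALSE)
    }
  }
  sigma_s <- m$sigma_s %||% 0
  if (sigma_s < 0 || sigma_s >= 1 / 3) {
    stop(sprintf("config error: model %d sigma_s must be in [0, 1/3)", i),
         call. = FALSE)
  }
  list(name = m$name %||% sprintf("model%d", i),
       spec = model_spec(subunits, n_points = m$n_points %||% 3000,
                         exclude_overlap = m$exclude_overlap %||% TRUE),
       n_bins = m$n_bins %||% 200,
       sigma_s = sigma_s, structure_factor = sf, params = params)
}

#' Run a simulation configuration
#'
#' Executes the full pipeline for every model in a [parse_config()] result
#' and writes, per model `<name>`: `pr_<name>.dat` (normalized p(r)),
#' `Iq_<name>.dat` (normalized intensity, plus the effective structure
#' factor as a third column when one is applied), `Isim_<name>.dat`
#' (simulated data, three columns), and `model_<name>.pdb` (bead model).
#' Every file header records the package version, the seed and the model
#' parameters. R_g and D_max per model are printed and returned. The seed
#' fully determines all output: rerunning with the same configuration
#' yields identical files.
#'
#' @param config A `run_config` from [parse_config()], or a path to one.
#' @param quiet Suppress the per-model summary printout.
#' @return Invisibly, a list per model with `name`, `rg`, `d_max`, `i0`,
#'   `files`, and the in-memory results from [simulate_experiment()].
#' @export
run_models <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  q <- default_q_grid(config$q_grid$min, config$q_grid$max,
                      config$q_grid$n_q, config$q_grid$spacing)
  set.seed(config$seed)
  ver <- as.character(utils::packageVersion("sasbead"))
  out <- lapply(config$models, function(m) {
    model <- build_point_model(m$spec)
    res <- simulate_experiment(model, q, params = m$params,
                               sigma_s = m$sigma_s,
                               sf = m$structure_factor, n_bins = m$n_bins)
    hdr <- c(sprintf("sasbead %s | seed %d | model '%s'", ver, config$seed,
                     m$name),
             sprintf("subunits: %s",
                     paste(vapply(m$spec$subunits, function(s) {
                       sprintf("%s(%s; dSLD=%g; com=%s)", s$kind,
                               paste(s$dims, collapse = ","), s$delta_sld,
                               paste(s$com, collapse = ","))
                     }, character(1)), collapse = " + ")),
             sprintf("n_points=%d n_bins=%d sigma_s=%g eta=%g exposure=%g sigma_rough=%g",
                     m$spec$n_points, m$n_bins, m$sigma_s, m$params$eta,
                     m$params$exposure, m$params$sigma_rough),
             if (!is.null(m$structure_factor)) {
               sprintf("structure_factor: %s", paste(
                 names(m$structure_factor),
                 unlist(m$structure_factor), sep = "=", collapse = " "))
             })
    f <- file.path(config$output_dir,
                   paste0(c("pr_", "Iq_", "Isim_", "model_"), m$name,
                          c(".dat", ".dat", ".dat", ".pdb")))
    .write_table(res$pr, f[1], c(hdr, "r [A]  p(r) [normalized]"))
    iq <- data.frame(q = res$curve$q, i = res$curve$intensity)
    iq_cols <- "q [1/A]  I_norm"
    if (!is.null(res$s_eff)) {
      iq$s_eff <- res$s_eff
      iq_cols <- "q [1/A]  I_norm  S_eff"
    }
    .write_table(iq, f[2], c(hdr, iq_cols))
    write_sas_dat(res$dataset, f[3], hdr)
    write_pdb(model, f[4])
    if (!quiet) {
      cat(sprintf("model '%s': R_g = %.2f A, D_max = %.2f A, I(0) = %.4g\n",
                  m$name, res$rg, res$d_max, res$i0))
    }
    list(name = m$name, rg = res$rg, d_max = res$d_max, i0 = res$i0,
         files = f, coords = model$coords, result = res)
  })
  invisible(out)
}

.write_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", header), con)
  utils::write.table(format(df, digits = 8, scientific = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}
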