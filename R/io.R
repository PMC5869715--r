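# File formats (project-defined CSV/JSON; headers fix the units), pipeline
# driver and command-line entry point.

#' Write a PES grid to CSV (with a JSON sidecar)
#'
#' Long-format CSV with columns `state,R,theta,phi,energy` (A, degrees,
#' kcal/mol); the sidecar `<path>.json` holds the surface spec, node lists
#' and noise/seed metadata for provenance.
#'
#' @param grid a [sample_grid()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "pes_grid"))
  rows <- do.call(rbind, lapply(names(grid$energy), function(st) {
    pts <- expand.grid(R = grid$R_nodes, theta = grid$theta_nodes,
                       phi = grid$phi_nodes, KEEP.OUT.ATTRS = FALSE)
    cbind(state = st, pts, energy = as.vector(grid$energy[[st]]))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  side <- list(units = list(R = "angstrom", theta = "degree", phi = "degree",
                            energy = "kcal/mol"),
               R_nodes = grid$R_nodes, theta_nodes = grid$theta_nodes,
               phi_nodes = grid$phi_nodes, noise_sd = grid$noise_sd,
               seed = grid$seed, spec = unclass(grid$spec))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a PES grid written by [write_grid()]
#'
#' @param path CSV path
#' @return a `pes_grid`
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("state", "R", "theta", "phi", "energy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_grid: missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$R <= 0)
  if (length(bad)) stop("read_grid: non-positive R at row ", bad[1])
  bad <- which(!is.finite(df$energy))
  if (length(bad)) stop("read_grid: non-finite energy at row ", bad[1])
  bad <- which(df$theta < 0 | df$theta > 180)
  if (length(bad)) stop("read_grid: theta outside [0, 180] at row ", bad[1])
  sidecar <- paste0(path, ".json")
  spec <- NULL
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$spec)) {
      spec <- side$spec
      spec$lambda_max <- as.integer(spec$lambda_max)
      class(spec) <- "surface_spec"
    }
  }
  Rn <- sort(unique(df$R)); tn <- sort(unique(df$theta)); pn <- sort(unique(df$phi))
  energy <- list()
  for (st in unique(df$state)) {
    sub <- df[df$state == st, ]
    o <- order(match(sub$phi, pn), match(sub$theta, tn), match(sub$R, Rn))
    if (nrow(sub) != length(Rn) * length(tn) * length(pn)) {
      stop("read_grid: state ", st, " is not a complete structured grid")
    }
    energy[[st]] <- array(sub$energy[o], dim = c(length(Rn), length(tn), length(pn)))
  }
  structure(list(R_nodes = Rn, theta_nodes = tn, phi_nodes = pn,
                 energy = energy, spec = spec, noise_sd = 0, seed = NULL),
            class = "pes_grid")
}

#' Write / read a fitted RKHS surface as JSON
#'
#' Stores the coefficient tensor, node lists, kernel spec, doming parameters
#' and fit diagnostics; the round trip is lossless to full double precision.
#'
#' @param surface an [fit_rkhs()] result
#' @param path output path
#' @return `path` invisibly (`write_surface`); an `rkhs_surface` (`read_surface`)
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "rkhs_surface"))
  obj <- unclass(surface)
  obj$beta_dim <- dim(surface$beta)
  obj$beta <- as.vector(surface$beta)
  obj$kernel <- unclass(obj$kernel)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- array(obj$beta, dim = obj$beta_dim)
  kern <- kernel_spec(obj$kernel$n, obj$kernel$m, obj$kernel$sigma_phi,
                      obj$kernel$regularization)
  structure(list(state = obj$state, beta = beta, R_nodes = obj$R_nodes,
                 phi_nodes = obj$phi_nodes, lambda_max = as.integer(obj$lambda_max),
                 kernel = kern, vc = obj$vc, asymptote = obj$asymptote,
                 diagnostics = obj$diagnostics),
            class = "rkhs_surface")
}

#' Write / read a rebinding ensemble as CSV (+ JSON metadata sidecar)
#'
#' One row per trajectory: `id, seed, stream, R0, theta0, tau_ps, censored,
#' phi_at_rebind, d_at_rebind`.
#'
#' @param ensemble a `rebinding_ensemble`
#' @param path output CSV path
#' @return `path` invisibly (`write_ensemble`); a `rebinding_ensemble`
#'   (`read_ensemble`)
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "rebinding_ensemble"))
  utils::write.csv(ensemble$records, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(ensemble$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "R0", "theta0", "tau_ps", "censored")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("read_ensemble: missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!rec$censored & !(rec$tau_ps > 0))
  if (length(bad)) stop("read_ensemble: non-positive rebinding time at row ", bad[1])
  if (anyDuplicated(rec$id)) stop("read_ensemble: duplicate trajectory ids")
  md <- list(n = nrow(rec), t_sim_ps = NA_real_)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) md <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(list(records = rec, metadata = md), class = "rebinding_ensemble")
}

#' Write / read a survival fit as JSON (Table-style columns)
#'
#' Serializes `rebinding_fraction, a1, tau1_ps, a2, tau2_ps, a3` plus the
#' residual and convergence flag.
#'
#' @param fit a [fit_survival()] result
#' @param path output path
#' @param rebinding_fraction optional empirical rebound fraction to embed
#' @return `path` invisibly (`write_fit`); a `survival_fit` (`read_fit`)
#' @export
write_fit <- function(fit, path, rebinding_fraction = NULL) {
  stopifnot(inherits(fit, "survival_fit"))
  obj <- list(rebinding_fraction = rebinding_fraction,
              a1 = fit$amplitudes[1], tau1_ps = fit$timescales_ps[1],
              a2 = if (fit$n_components > 1) fit$amplitudes[2],
              tau2_ps = if (fit$n_components > 1) fit$timescales_ps[2],
              a3 = fit$static, residual = fit$residual,
              converged = fit$converged, n_components = fit$n_components,
              n_parameters = fit$n_parameters)
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- as.integer(obj$n_components %||% (1 + !is.null(obj$tau2_ps)))
  amplitudes <- c(obj$a1, if (k > 1) obj$a2)
  timescales <- c(obj$tau1_ps, if (k > 1) obj$tau2_ps)
  structure(list(amplitudes = amplitudes, timescales_ps = timescales,
                 static = obj$a3 %||% 0, residual = obj$residual %||% NA_real_,
                 converged = isTRUE(obj$converged), n_components = k,
                 n_parameters = obj$n_parameters %||% (2 * k + 1)),
            class = "survival_fit")
}

#' Run the full pipeline from a configuration
#'
#' Executes grid generation, RKHS fitting, adiabatic scan, rebinding
#' dynamics, kinetics fitting and structural analysis as requested, writing
#' each artifact (with the resolved configuration embedded for provenance)
#' under `config$out_dir`. Configuration may be a named list or a path to a
#' JSON file with the same keys.
#'
#' @param config list or JSON path. Keys (with defaults):
#'   `stages` (character subset of `grid`, `fit`, `scan`, `rebind`,
#'   `kinetics`, `analyze`), `out_dir`, `delta` (7.5), `mix_width` (0.5),
#'   `solvent` ("glycerol_water"), `temperature` (300), `n` (50),
#'   `t_sim_ps` (20), `seed` (1), `components` (2), `with_static` (TRUE)
#' @return named list of artifact paths and in-memory results
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(stages = c("grid", "fit", "scan", "rebind", "kinetics", "analyze"),
         out_dir = ".", delta = 7.5, mix_width = 0.5,
         solvent = "glycerol_water", temperature = 300, n = 50,
         t_sim_ps = 20, seed = 1, components = 2, with_static = TRUE),
    as.list(config))
  if (!cfg$solvent %in% c("gas", "water", "glycerol_water", "water_ions")) {
    stop("run_pipeline: unknown solvent label `", cfg$solvent, "`")
  }
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed)) {
    stop("run_pipeline: seed must be a non-negative integer")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(cfg$out_dir, f)
  out <- list(config = cfg)

  ref <- make_reference_surfaces(surface_spec())
  grid <- sample_grid(ref)
  if ("grid" %in% cfg$stages) out$grid_csv <- write_grid(grid, pth("grid.csv"))
  s2 <- fit_rkhs(grid, "doublet")
  s4 <- fit_rkhs(grid, "quartet")
  if ("fit" %in% cfg$stages) {
    out$surface_2A_json <- write_surface(s2, pth("surf_2A.json"))
    out$surface_4A_json <- write_surface(s4, pth("surf_4A.json"))
  }
  env <- if (cfg$solvent == "gas") "gas" else cfg$solvent
  model <- two_state_model(s2, s4, delta = cfg$delta, mix_width = cfg$mix_width,
                           environment = env)
  if ("scan" %in% cfg$stages) {
    scan <- adiabatic_scan(model, "theta", c(10, 170), fixed = list(R = 2.4))
    utils::write.csv(scan, pth("scan.csv"), row.names = FALSE, quote = FALSE)
    out$scan_csv <- pth("scan.csv")
    out$barriers <- locate_barriers(scan)$barriers
  }
  if ("rebind" %in% cfg$stages) {
    solvent <- solvent_model(cfg$solvent, temperature = cfg$temperature)
    bound <- sample_bound_ensemble(model, solvent, n = cfg$n, seed = cfg$seed)
    post <- photodissociate(bound, model, solvent, seed = cfg$seed + 1)
    ens <- run_ensemble(post, model, solvent, t_sim_ps = cfg$t_sim_ps,
                        seed = cfg$seed + 2)
    out$ensemble <- ens
    out$ensemble_csv <- write_ensemble(ens, pth("ensemble.csv"))
    if ("kinetics" %in% cfg$stages) {
      curve <- survival_curve(ens)
      fit <- fit_survival(curve, n_components = cfg$components,
                          with_static = cfg$with_static, seed = cfg$seed)
      out$fit <- fit
      out$fit_json <- write_fit(fit, pth("fit.json"),
                                rebinding_fraction = rebinding_fraction(ens))
    }
    if ("analyze" %in% cfg$stages) {
      clusters <- classify_by_rebinding_time(ens)
      analysis <- list(
        clusters = lapply(clusters$classes, function(cl)
          list(label = cl$label, n = cl$n, centroid = as.list(cl$centroid),
               frac_close = cl$frac_close)),
        rebinding_fraction = rebinding_fraction(ens),
        config = cfg)
      if (any(!ens$records$censored)) {
        oop <- oop_distribution(ens)
        analysis$domed_fraction <- oop$domed_fraction
      }
      jsonlite::write_json(analysis, pth("analysis.json"), auto_unbox = TRUE,
                           digits = NA)
      out$analysis_json <- pth("analysis.json")
      out$analysis <- analysis
    }
  }
  out
}

# --- minimal command-line front end -----------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      out[[key]] <- TRUE; i <- i + 1
    } else {
      val <- args[[i + 1]]
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num)) num else val
      i <- i + 2
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the pipeline verbs (`make-grid`, `fit-pes`, `scan`, `rebind`,
#' `isomerize`, `fit-kinetics`, `analyze`, `run`). Invoked by the
#' `inst/cli/hemekin` script as `hemekin <verb> --key value ...`.
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly
#' @export
hemekin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: hemekin <make-grid|fit-pes|scan|rebind|isomerize|fit-kinetics|analyze|run> [--key value ...]\n")
    return(invisible(1L))
  }
  verb <- args[[1]]
  opt <- parse_cli_args(args[-1])
  status <- tryCatch({
    switch(verb,
      "make-grid" = {
        ref <- make_reference_surfaces(surface_spec())
        write_grid(sample_grid(ref), opt$out %||% "grid.csv")
      },
      "fit-pes" = {
        grid <- read_grid(opt$grid %||% "grid.csv")
        st <- opt$state %||% "doublet"
        write_surface(fit_rkhs(grid, st), opt$out %||% paste0("surf_", st, ".json"))
      },
      "scan" = {
        model <- default_two_state_model(delta = opt$delta %||% 5)
        scan <- adiabatic_scan(model, opt$vary %||% "theta",
                               c(opt$from %||% 10, opt$to %||% 170),
                               fixed = list(R = opt$R %||% 2.4))
        utils::write.csv(scan, opt$out %||% "scan.csv", row.names = FALSE,
                         quote = FALSE)
      },
      "rebind" = {
        res <- run_pipeline(utils::modifyList(
          list(stages = c("rebind"),
               out_dir = dirname(opt$out %||% "ensemble.csv")), opt))
        file.rename(res$ensemble_csv, opt$out %||% "ensemble.csv")
      },
      "isomerize" = {
        model <- default_two_state_model(delta = opt$delta %||% 7.5)
        ens <- isomerization_ensemble(model, opt$environment %||% "gas",
                                      n = opt$n %||% 50,
                                      t_sim_ps = opt$t_sim %||% 100,
                                      seed = opt$seed %||% 1)
        write_ensemble(ens, opt$out %||% "iso.csv")
      },
      "fit-kinetics" = {
        ens <- read_ensemble(opt$ensemble %||% "ensemble.csv")
        curve <- survival_curve(ens, t_sim_ps = opt$t_sim %||% ens$metadata$t_sim_ps)
        fit <- fit_survival(curve, n_components = opt$components %||% 2,
                            with_static = !isFALSE(opt$static))
        write_fit(fit, opt$out %||% "fit.json",
                  rebinding_fraction = rebinding_fraction(ens))
      },
      "analyze" = {
        ens <- read_ensemble(opt$ensemble %||% "ensemble.csv")
        cl <- classify_by_rebinding_time(ens)
        res <- list(clusters = lapply(cl$classes, function(x)
          list(label = x$label, n = x$n, centroid = as.list(x$centroid),
               frac_close = x$frac_close)),
          rebinding_fraction = rebinding_fraction(ens))
        jsonlite::write_json(res, opt$out %||% "analysis.json",
                             auto_unbox = TRUE, digits = NA)
      },
      "run" = {
        cfg <- if (!is.null(opt$config)) opt$config else opt
        run_pipeline(cfg)
      },
      stop("unknown verb: ", verb))
    0L
  }, error = function(e) {
    message("hemekin: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
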