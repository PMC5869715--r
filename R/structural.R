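# Structural/kinetic correlation analyses of rebinding ensembles.

#' Iron out-of-plane distribution at the moment of rebinding
#'
#' Normalized histogram of the Fe-oop distance d (A) recorded at the first
#' frame of each trajectory's sustained rebinding window, over rebound
#' trajectories only, plus the fraction with the iron displaced beyond the
#' doming threshold (one-sided: d > threshold counts as a domed rebinding
#' geometry).
#'
#' @param ensemble a `rebinding_ensemble`
#' @param threshold doming threshold, A (default 0.1)
#' @param breaks histogram break specification (passed to [hist()])
#' @return object of class `oop_distribution`: `density` histogram (mass
#'   sums to 1), `domed_fraction`, `threshold`, `n_rebound`
#' @export
oop_distribution <- function(ensemble, threshold = 0.1, breaks = 30) {
  rec <- if (inherits(ensemble, "rebinding_ensemble")) ensemble$records else
    as.data.frame(ensemble)
  d <- rec$d_at_rebind[!rec$censored & is.finite(rec$d_at_rebind)]
  if (length(d) == 0) stop("oop_distribution: no rebound trajectories with recorded d")
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  mass <- h$counts / sum(h$counts)
  structure(list(mids = h$mids, breaks = h$breaks, mass = mass,
                 domed_fraction = mean(d > threshold),
                 threshold = threshold, n_rebound = length(d)),
            class = "oop_distribution")
}

#' @export
print.oop_distribution <- function(x, ...) {
  cat(sprintf("Fe-oop distribution at rebinding: %d events, P(d > %.2f A) = %.3f\n",
              x$n_rebound, x$threshold, x$domed_fraction))
  invisible(x)
}

#' Cluster trajectories by rebinding timescale
#'
#' Fixed-boundary partition into `short` (tau below the first bound),
#' `intermediate` (between the bounds) and `long` (censored, i.e. no
#' rebinding within t_sim) classes, with the per-class centroid of the
#' post-photodissociation (R0, theta0) positions and the fraction of each
#' class that starts close to the state-crossing region (R0 < `R_close`).
#'
#' @param ensemble a `rebinding_ensemble`
#' @param bounds numeric `c(short_max_ps, t_sim_ps)`
#' @param R_close crossing-proximity radius, A (default 4)
#' @return object of class `timescale_clusters`
#' @export
classify_by_rebinding_time <- function(ensemble, bounds = NULL, R_close = 4) {
  rec <- if (inherits(ensemble, "rebinding_ensemble")) ensemble$records else
    as.data.frame(ensemble)
  if (nrow(rec) == 0) stop("classify_by_rebinding_time: empty ensemble")
  if (is.null(bounds)) {
    t_sim <- if (inherits(ensemble, "rebinding_ensemble"))
      ensemble$metadata$t_sim_ps else max(rec$tau_ps, na.rm = TRUE)
    bounds <- c(20, t_sim)
  }
  cls <- ifelse(rec$censored, "long",
                ifelse(rec$tau_ps <= bounds[1], "short", "intermediate"))
  out <- lapply(c("short", "intermediate", "long"), function(lab) {
    sel <- cls == lab
    if (!any(sel)) {
      return(list(label = lab, n = 0L, ids = integer(0),
                  centroid = c(R = NA_real_, theta = NA_real_),
                  frac_close = NA_real_, empty = TRUE))
    }
    list(label = lab, n = sum(sel),
         ids = if (!is.null(rec$id)) rec$id[sel] else which(sel),
         centroid = c(R = mean(rec$R0[sel]), theta = mean(rec$theta0[sel])),
         frac_close = mean(rec$R0[sel] < R_close), empty = FALSE)
  })
  names(out) <- c("short", "intermediate", "long")
  structure(list(classes = out, bounds = bounds, R_close = R_close,
                 n = nrow(rec)),
            class = "timescale_clusters")
}

#' @export
print.timescale_clusters <- function(x, ...) {
  cat(sprintf("Rebinding-time clusters (bounds %g ps / %g ps):\n",
              x$bounds[1], x$bounds[2]))
  for (cl in x$classes) {
    if (cl$empty) {
      cat(sprintf("  %-12s empty\n", cl$label))
    } else {
      cat(sprintf("  %-12s n = %4d, centroid (%.2f A, %.0f deg), frac(R0 < %g A) = %.2f\n",
                  cl$label, cl$n, cl$centroid[1], cl$centroid[2], x$R_close,
                  cl$frac_close))
    }
  }
  invisible(x)
}

#' Fraction of trajectories rebinding within a time window
#'
#' @param ensemble a `rebinding_ensemble`
#' @param t window end, ps; must not exceed the censoring time
#' @return `count(tau <= t) / n`
#' @export
fraction_rebinding_within <- function(ensemble, t) {
  rec <- if (inherits(ensemble, "rebinding_ensemble")) ensemble$records else
    as.data.frame(ensemble)
  t_sim <- if (inherits(ensemble, "rebinding_ensemble"))
    ensemble$metadata$t_sim_ps else Inf
  if (t > t_sim) {
    stop("fraction_rebinding_within: t exceeds the censoring time (undefined count)")
  }
  mean(!rec$censored & rec$tau_ps <= t)
}
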