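## Trajectory access and CSV round-trip.

#' @describeIn Trajectory time points
#' @export
setMethod("trajTimes", "Trajectory", function(object) object@times)

#' @describeIn Trajectory value matrix (rows = times, columns = species)
#' @export
setMethod("trajValues", "Trajectory", function(object) object@values)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("%s: %d species, %d time points on [%g, %g]\n", class(object),
              ncol(object@values), length(object@times),
              min(object@times), max(object@times)))
})

.checkSpecies <- function(object, species) {
  bad <- setdiff(species, colnames(object@values))
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "))
}

#' Value of a species at a time point
#'
#' Continuous trajectories (ODE, LNA, path means) are interpolated linearly;
#' SSA paths are piecewise constant between jumps.
#'
#' @param object a [Trajectory-class]
#' @param species species name (single)
#' @param t time (vectorised)
#' @return numeric vector of values
#' @export
setMethod("speciesAt", "Trajectory", function(object, species, t) {
  .checkSpecies(object, species)
  stats::approx(object@times, object@values[, species], xout = t,
                rule = 2)$y
})

#' @describeIn speciesAt piecewise-constant lookup on the exact jump path
#' @export
setMethod("speciesAt", "SsaPath", function(object, species, t) {
  .checkSpecies(object, species)
  idx <- findInterval(t, object@times)
  idx[idx < 1] <- 1L
  object@values[idx, species]
})

#' Standard deviation of a species at a time point
#'
#' Zero for deterministic and single SSA trajectories; the Gaussian standard
#' deviation for LNA trajectories (linear interpolation).
#' @inheritParams speciesAt
#' @export
setMethod("sdAt", "Trajectory", function(object, species, t) {
  .checkSpecies(object, species)
  rep(0, length(t))
})

#' @rdname sdAt
#' @export
setMethod("sdAt", "LnaTrajectory", function(object, species, t) {
  .checkSpecies(object, species)
  stats::approx(object@times, object@sd[, species], xout = t, rule = 2)$y
})

#' @export
as.data.frame.Trajectory <- function(x, ...) {
  data.frame(time = x@times, x@values, check.names = FALSE)
}

#' Write a trajectory to CSV
#'
#' Column 1 is \code{time}, followed by one column per species in species
#' declaration order; LNA trajectories append \code{sd:<species>} columns.
#' The writer keeps full double precision so the read/write round trip is
#' lossless.
#'
#' @param traj a [Trajectory-class]
#' @param path file path
#' @export
writeTrajectoryCSV <- function(traj, path) {
  df <- as.data.frame(traj)
  if (is(traj, "LnaTrajectory")) {
    sd <- traj@sd
    colnames(sd) <- paste0("sd:", colnames(sd))
    df <- cbind(df, sd)
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [writeTrajectoryCSV()]
#' @param path file path
#' @return an [OdeTrajectory-class] (or [LnaTrajectory-class] when
#'   \code{sd:} columns are present)
#' @export
readTrajectoryCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sdCols <- grep("^sd:", colnames(df))
  vals <- as.matrix(df[, setdiff(seq_along(df), c(1L, sdCols)), drop = FALSE])
  if (length(sdCols)) {
    sd <- as.matrix(df[, sdCols, drop = FALSE])
    colnames(sd) <- sub("^sd:", "", colnames(sd))
    new("LnaTrajectory", times = df$time, values = vals, sd = sd,
        cov = array(NA_real_, c(0, 0, 0)))
  } else {
    new("OdeTrajectory", times = df$time, values = vals)
  }
}
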