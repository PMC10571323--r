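# Result output: VTU snapshot series with a PVD collection, and CSV traces
# of min/max/pointwise potential values over time.

#' Write simulation outputs
#'
#' Writes the recorded snapshots as a VTU time series (potential in tissue
#' units and rescaled to millivolts, plus the activation map in ms on the
#' final snapshot) referenced by a PVD collection file, and/or the min/max
#' and probe traces as CSV.
#'
#' @param result a [run_simulation()] result with recorded snapshots
#'   (`output$every > 0` in the problem).
#' @param dir output directory (created if missing).
#' @param basename prefix for VTU/PVD files.
#' @param vtu write the VTU series?
#' @param csv write the CSV trace?
#' @param csv_file CSV file name (inside `dir`).
#' @return named list of written paths, invisibly.
#' @export
write_outputs <- function(result, dir = ".", basename = "monodomain",
                          vtu = TRUE, csv = TRUE,
                          csv_file = paste0(basename, "_trace.csv")) {
  stopifnot(inherits(result, "monodomain_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prob <- result$problem
  mesh <- prob$partition$mesh
  nn <- nrow(mesh$nodes)
  # rescale through the first conductive model (mixed-model runs share the
  # tissue unit, the mV map may differ per region and is indicative only)
  mod <- NULL
  for (m in prob$models) if (!is.null(m)) { mod <- m; break }
  written <- list()
  if (vtu) {
    if (!length(result$snapshots)) {
      stop("no snapshots recorded; set output$every > 0 in the problem")
    }
    files <- character(length(result$snapshots))
    for (k in seq_along(result$snapshots)) {
      u <- result$snapshots[[k]][seq_len(nn)]
      pd <- list(u = u,
                 u_mV = rescale_potential(mod, u / mod$unit_scale))
      if (k == length(result$snapshots)) {
        act <- result$activation$time[seq_len(nn)] * 1000
        act[is.na(act)] <- -1  # "never activated" sentinel for viewers
        pd$activation_ms <- act
      }
      files[k] <- sprintf("%s_%04d.vtu", basename, k - 1L)
      write_vtu(mesh, file.path(dir, files[k]), point_data = pd)
    }
    pvd <- file.path(dir, paste0(basename, ".pvd"))
    con <- file(pvd, "wt")
    writeLines('<?xml version="1.0"?>', con)
    writeLines('<VTKFile type="Collection" version="0.1">', con)
    writeLines('  <Collection>', con)
    for (k in seq_along(files)) {
      writeLines(sprintf('    <DataSet timestep="%s" file="%s"/>',
                         .fmt_num(result$times[k]), files[k]), con)
    }
    writeLines(c('  </Collection>', '</VTKFile>'), con)
    close(con)
    written$vtu <- file.path(dir, files)
    written$pvd <- pvd
  }
  if (csv) {
    if (is.null(result$trace)) {
      stop("no trace recorded; set output$every > 0 in the problem")
    }
    path <- file.path(dir, csv_file)
    con <- file(path, "wt")
    writeLines("# units: time s, potential in tissue units (V for mV-based models)", con)
    utils::write.csv(result$trace, con, row.names = FALSE)
    close(con)
    written$csv <- path
  }
  invisible(written)
}
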