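#' Write a WKB solution as columnar text
#'
#' Columns: x (m), Re/Im k (1/m), |p| (Pa), arg p (rad), |V| (m/s), arg V
#' (rad).  Unit-annotated header; atomic write.
#'
#' @param wkb A `wkb_solution`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wkb_csv <- function(wkb, path) {
  d <- tidy(wkb)
  names(d) <- c("x_m", "k_re_per_m", "k_im_per_m", "p_abs_Pa", "p_arg_rad",
                "V_abs_m_per_s", "V_arg_rad", "wkb_ratio")
  atomic_write(path, function(p) utils::write.csv(d, p, row.names = FALSE))
  invisible(path)
}

#' Write a 2-D field as columnar text
#'
#' Cell-centred long format with unit-annotated column names.
#'
#' @param field An `oscillatory_field` or `streaming_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  d <- tidy(field)
  nm <- names(d)
  nm[nm == "x"] <- "x_m"; nm[nm == "y"] <- "y_m"
  nm <- ifelse(nm %in% c("x_m", "y_m", "chamber"), nm, paste0(nm, "_m_per_s"))
  nm[grepl("^p_abs", nm)] <- "p_abs_Pa"
  names(d) <- nm
  atomic_write(path, function(p) utils::write.csv(d, p, row.names = FALSE))
  invisible(path)
}

#' Write a field as a legacy-VTK structured grid
#'
#' ASCII VTK ("STRUCTURED_GRID") with the cell-centred velocity components
#' as point data; complex oscillatory fields are written as real and
#' imaginary parts, streaming fields as their Eulerian, drift and Lagrangian
#' components.  Readable by ParaView and by most scientific VTK readers.
#'
#' @param field An `oscillatory_field` or `streaming_field`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path) {
  geom <- field$geom
  nx <- geom$Nx; ny <- geom$Ny
  pts <- cbind(rep(geom$xc, ny), rep(geom$yc, each = nx), 0)
  if (inherits(field, "oscillatory_field")) {
    ucc <- u_at_cc(geom, field$u); vcc <- v_at_cc(geom, field$v)
    scalars <- list(u_re = Re(ucc), u_im = Im(ucc),
                    v_re = Re(vcc), v_im = Im(vcc),
                    p_re = Re(field$p), p_im = Im(field$p))
  } else if (inherits(field, "streaming_field")) {
    scalars <- list(u_euler = u_at_cc(geom, field$u_euler),
                    v_euler = v_at_cc(geom, field$v_euler),
                    u_sd = u_at_cc(geom, field$u_sd),
                    v_sd = v_at_cc(geom, field$v_sd),
                    u_ss = u_at_cc(geom, field$u_ss),
                    v_ss = v_at_cc(geom, field$v_ss))
  } else abort("unsupported field type")
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 "otostream field (SI units)", "ASCII",
                 "DATASET STRUCTURED_GRID",
                 sprintf("DIMENSIONS %d %d 1", nx, ny),
                 sprintf("POINTS %d double", nx * ny)), con)
    utils::write.table(format(pts, digits = 9, scientific = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    writeLines(sprintf("POINT_DATA %d", nx * ny), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.vector(scalars[[nm]]), digits = 9,
                        scientific = TRUE), con)
    }
  })
  invisible(path)
}

#' Write particle trajectories as columnar text
#'
#' @param ensemble A `particle_ensemble` with recorded trajectories.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(ensemble, path) {
  tr <- attr(ensemble, "trajectories")
  if (is.null(tr)) abort("ensemble has no recorded trajectories")
  names(tr) <- c("particle_id", "t_s", "x_m", "y_m")
  atomic_write(path, function(p) utils::write.csv(tr, p, row.names = FALSE))
  invisible(path)
}
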