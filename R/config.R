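#' Read and resolve a run configuration
#'
#' Run configurations are YAML files with sections `membrane`, `fluid`,
#' `geometry`, `stimulus`, `particle`, `solver`, plus top-level `seed` and
#' `schema` version.  Missing fields fall back to package defaults, so a
#' minimal config may contain only a stimulus.  The resolved configuration
#' round-trips losslessly through [write_run_manifest()].
#'
#' @param path Path to a YAML config file, or a list with the same
#'   structure.
#' @return A list of class `run_config` with constructed objects:
#'   `props` ([membrane_properties()]), `fluid`, `geom`, `tones`,
#'   `particles`, `solver` ([oracle_settings()]), `seed`, and the raw
#'   resolved `config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) abort("config must be a YAML mapping")
  bad <- setdiff(names(cfg), c("membrane", "fluid", "geometry", "stimulus",
                               "particle", "solver", "seed", "schema"))
  if (length(bad))
    abort(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")))

  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  m <- cfg$membrane %||% list()
  props <- membrane_properties(
    m0 = num(m$m0) %||% 32e-12, K0 = num(m$K0) %||% 1,
    x_ref = num(m$x_ref) %||% 7e-3, m_ref = num(m$m_ref) %||% 65e-12,
    K_ref = num(m$K_ref) %||% 0.03,
    strip_width = num(m$strip_width) %||% 8e-6,
    strip_breadth = num(m$strip_breadth) %||% 186e-6,
    xi_by_spl = if (!is.null(m$xi_by_spl)) unlist(m$xi_by_spl)
    else c(`60` = 10e-9, `80` = 500e-9, `100` = 2000e-9))

  fcfg <- cfg$fluid %||% list()
  fluid <- fluid_properties(rho0 = num(fcfg$rho0) %||% 1000,
                            nu = num(fcfg$nu) %||% 1e-6)

  g <- cfg$geometry %||% list()
  res <- g$resolution %||% "default"
  res_dx <- c(coarse = 50e-6, default = 20e-6, fine = 11.2e-6)
  if (!res %in% names(res_dx))
    abort("geometry$resolution must be coarse, default or fine")
  geom <- cochlea_geometry(
    L = num(g$L) %||% 7e-3, h = num(g$h) %||% 0.5e-3,
    helicotrema_len = num(g$helicotrema_len) %||% 0.5e-3,
    dx = num(g$dx) %||% res_dx[[res]],
    dy_max = num(g$dy_max) %||% 25e-6,
    growth = num(g$growth) %||% 1.2,
    f_max = num(g$f_max) %||% 20e3, fluid = fluid,
    stokes_cells = num(g$stokes_cells) %||% 3)

  s <- cfg$stimulus
  if (is.null(s)) abort("config needs a `stimulus` section", class = "otostream_no_stimulus")
  type <- s$type %||% if (!is.null(s$f)) "tone" else "comb"
  tones <- switch(
    type,
    tone = tone(num(s$f), spl = num(s$spl) %||% 80,
                phase = num(s$phase) %||% 0),
    comb = {
      map <- tonotopic_map(props)
      comb_from_delta(map, n = num(s$n) %||% 10,
                      delta = num(s$delta), R = num(s$R),
                      spl = num(s$spl) %||% 80, f1 = num(s$f1),
                      x_top = num(s$x_top) %||% 0.25e-3,
                      x_max = geom$L)
    },
    abort("stimulus$type must be 'tone' or 'comb'"))

  p <- cfg$particle %||% list()
  particles <- particle_properties(
    diameter = num(p$diameter) %||% 200e-9,
    density = num(p$density) %||% fluid$rho0,
    restitution = num(p$restitution) %||% 0.95,
    friction = num(p$friction) %||% 1e-3,
    count = num(p$count) %||% 5000)

  sv <- cfg$solver %||% list()
  solver <- oracle_settings(
    steps_per_cycle = num(sv$steps_per_cycle) %||% 64,
    n_cycles = num(sv$n_cycles) %||% 12,
    transient_cycles = num(sv$transient_cycles) %||% 5,
    courant_cap = num(sv$courant_cap) %||% 0.9,
    theta = num(sv$theta) %||% 0.5)

  structure(list(props = props, fluid = fluid, geom = geom, tones = tones,
                 particles = particles, solver = solver,
                 seed = as.integer(cfg$seed %||% 1L),
                 schema = cfg$schema %||% 1L, config = cfg),
            class = "run_config")
}

#' Write the resolved run manifest
#'
#' Every run records the exact resolved configuration, package version and
#' seed next to its outputs, so a run can be reproduced from its manifest
#' alone.  Written atomically (temp file + rename).
#'
#' @param rc A `run_config` from [read_run_config()].
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  manifest <- list(
    schema = rc$schema,
    package_version = as.character(utils::packageVersion("otostream")),
    seed = rc$seed,
    membrane = list(m0 = rc$props$m0, K0 = rc$props$K0,
                    x_ref = rc$props$x_ref, m_ref = rc$props$m_ref,
                    K_ref = rc$props$K_ref, l_m = rc$props$l_m,
                    l_K = rc$props$l_K, A = rc$props$A,
                    xi_by_spl = as.list(rc$props$xi_by_spl)),
    fluid = list(rho0 = rc$fluid$rho0, nu = rc$fluid$nu),
    geometry = list(L = rc$geom$L, h = rc$geom$h,
                    helicotrema_len = rc$geom$helicotrema_len,
                    Nx = rc$geom$Nx, Ny = rc$geom$Ny, dx = rc$geom$dx),
    stimulus = lapply(split(rc$tones, seq_len(nrow(rc$tones))), function(t)
      list(f = t$f, spl = t$spl, phase = t$phase)),
    particle = unclass(rc$particles),
    solver = unclass(rc$solver))
  atomic_write(path, function(p) yaml::write_yaml(manifest, p))
  invisible(path)
}

# all file writes go through temp + rename
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort(sprintf("could not write %s", path))
  invisible(path)
}
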