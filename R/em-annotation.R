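#' Annotated presynaptic terminal geometry
#'
#' Holds the traced geometry of one mossy fiber terminal from an electron
#' micrograph: the terminal outline, organelle outlines (mitochondria
#' etc.), active-zone polylines, and vesicle centers with diameters. All
#' coordinates are continuous nm.
#'
#' @param terminal Closed terminal polygon: n x 2 matrix (nm).
#' @param organelles List of closed organelle polygons (nm).
#' @param active_zones List of active-zone polylines, each an n x 2 matrix
#'   (nm) with at least 2 vertices.
#' @param vesicles Tibble/data frame with columns `x_nm`, `y_nm`,
#'   `diameter_nm` (> 0); centers must lie inside the terminal polygon.
#' @param scale_nm_per_px Acquisition scale metadata (nm per pixel).
#' @return A list of class `terminal_annotation`.
#' @export
terminal_annotation <- function(terminal, organelles = list(),
                                active_zones = list(),
                                vesicles = NULL, scale_nm_per_px = 1) {
  terminal <- check_polygon(terminal, "terminal polygon")
  organelles <- lapply(organelles, check_polygon, what = "organelle polygon")
  active_zones <- lapply(active_zones, function(l) {
    l <- as.matrix(l)
    if (nrow(l) < 2 || polyline_length_nm(l) <= 0) {
      abort("Zero-length active-zone polyline.")
    }
    l
  })
  if (is.null(vesicles)) {
    vesicles <- tibble::tibble(x_nm = numeric(), y_nm = numeric(),
                               diameter_nm = numeric())
  }
  vesicles <- tibble::as_tibble(vesicles)
  stopifnot(all(c("x_nm", "y_nm", "diameter_nm") %in% names(vesicles)))
  if (nrow(vesicles) > 0) {
    if (any(vesicles$diameter_nm <= 0)) abort("Vesicle diameters must be > 0.")
    inside <- points_in_polygon(vesicles$x_nm, vesicles$y_nm, terminal,
                                boundary = TRUE)
    if (!all(inside)) abort("All vesicle centers must lie inside the terminal.")
  }
  structure(list(terminal = terminal, organelles = organelles,
                 active_zones = active_zones, vesicles = vesicles,
                 scale_nm_per_px = scale_nm_per_px),
            class = "terminal_annotation")
}

#' @export
print.terminal_annotation <- function(x, ...) {
  cat(sprintf(paste0(
    "<terminal_annotation> area %.2f um^2, %d organelle(s), ",
    "%d active zone(s), %d vesicle(s)\n"),
    polygon_area_nm2(x$terminal) / 1e6, length(x$organelles),
    length(x$active_zones), nrow(x$vesicles)))
  invisible(x)
}

#' Read / write terminal annotations as JSON
#'
#' The JSON file stores raw pixel coordinates plus `scale_nm_per_px`;
#' coordinates are converted to nm on load and back to pixels on write.
#' Keys: `terminal`, `organelles`, `active_zones`, `vesicles` (each vesicle
#' is `[x, y, diameter]`), `scale_nm_per_px`.
#'
#' @param path File path.
#' @return `read_terminal_annotation()` returns a [terminal_annotation()];
#'   the writer returns `path` invisibly.
#' @export
read_terminal_annotation <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  s <- j$scale_nm_per_px %||% 1
  # jsonlite may simplify a list of polygons to a matrix or 3-d array
  as_poly_list <- function(x) {
    if (is.null(x) || length(x) == 0) return(list())
    if (is.array(x) && length(dim(x)) == 3) {
      return(lapply(seq_len(dim(x)[1]), function(i) x[i, , ]))
    }
    if (is.matrix(x)) return(list(x))
    lapply(x, as.matrix)
  }
  ves <- if (is.null(j$vesicles) || length(j$vesicles) == 0) {
    NULL
  } else {
    vm <- as.matrix(j$vesicles)
    tibble::tibble(x_nm = vm[, 1] * s, y_nm = vm[, 2] * s,
                   diameter_nm = vm[, 3] * s)
  }
  terminal_annotation(
    terminal = as.matrix(j$terminal) * s,
    organelles = lapply(as_poly_list(j$organelles), function(m) m * s),
    active_zones = lapply(as_poly_list(j$active_zones), function(m) m * s),
    vesicles = ves,
    scale_nm_per_px = s
  )
}

#' @rdname read_terminal_annotation
#' @param annotation A [terminal_annotation()].
#' @export
write_terminal_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "terminal_annotation"))
  s <- annotation$scale_nm_per_px
  j <- list(
    terminal = annotation$terminal / s,
    organelles = lapply(annotation$organelles, function(m) m / s),
    active_zones = lapply(annotation$active_zones, function(m) m / s),
    vesicles = unname(as.matrix(annotation$vesicles)) / s,
    scale_nm_per_px = s
  )
  jsonlite::write_json(j, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Simulate an annotated terminal with a Poisson vesicle pattern
#'
#' Places vesicle centers as a homogeneous Poisson process inside the
#' terminal polygon (excluding organelles), with truncated-normal diameters
#' (hard floor 10 nm). Optionally adds an enrichment band of extra vesicles
#' within `proximity_nm` of each active zone, emulating the release-site
#' clusters seen in micrographs.
#'
#' @param density_per_um2 Background vesicle density (um^-2, >= 0).
#' @param diameter_mean_nm,diameter_sd_nm Diameter distribution (nm);
#'   defaults 33.5 and 3, the wild-type mossy-fiber values.
#' @param terminal Terminal polygon (nm); default a square of 10 um^2.
#' @param organelles List of organelle polygons (nm).
#' @param active_zones List of AZ polylines (nm).
#' @param az_extra_per_az Mean number of extra enrichment vesicles placed
#'   within `proximity_nm` of each active zone (Poisson).
#' @param proximity_nm Width of the enrichment band (nm).
#' @param seed Optional integer seed.
#' @return A [terminal_annotation()] with attribute `truth` = list of the
#'   generator parameters and realized counts.
#' @export
simulate_terminal <- function(density_per_um2 = 131.7,
                              diameter_mean_nm = 33.5, diameter_sd_nm = 3,
                              terminal = NULL, organelles = list(),
                              active_zones = list(), az_extra_per_az = 0,
                              proximity_nm = 100, seed = NULL) {
  stopifnot(density_per_um2 >= 0, diameter_sd_nm >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(terminal)) {
    side <- sqrt(10 * 1e6)  # 10 um^2 square, nm
    terminal <- cbind(c(0, side, side, 0), c(0, 0, side, side))
  }
  terminal <- check_polygon(terminal, "terminal polygon")
  organelles <- lapply(organelles, check_polygon, what = "organelle polygon")
  area_um2 <- polygon_area_nm2(terminal) / 1e6
  free_area_um2 <- area_um2 -
    sum(vapply(organelles, polygon_area_nm2, numeric(1))) / 1e6
  n_bg <- rpois(1, density_per_um2 * free_area_um2)
  pts <- sample_points_in_region(n_bg, terminal, organelles)
  if (az_extra_per_az > 0 && length(active_zones) > 0) {
    for (az in active_zones) {
      n_extra <- rpois(1, az_extra_per_az)
      if (n_extra > 0) {
        extra <- sample_points_near_polyline(n_extra, az, proximity_nm,
                                             terminal, organelles)
        pts <- rbind(pts, extra)
      }
    }
  }
  n_total <- nrow(pts)
  diam <- rtruncnorm_floor(n_total, diameter_mean_nm, diameter_sd_nm,
                           floor = 10)
  ves <- tibble::tibble(x_nm = pts[, 1], y_nm = pts[, 2], diameter_nm = diam)
  ann <- terminal_annotation(terminal, organelles, active_zones, ves)
  attr(ann, "truth") <- list(density_per_um2 = density_per_um2,
                             diameter_mean_nm = diameter_mean_nm,
                             diameter_sd_nm = diameter_sd_nm,
                             n_background = n_bg, n_total = n_total,
                             free_area_um2 = free_area_um2)
  ann
}

sample_points_in_region <- function(n, terminal, organelles,
                                    max_tries = 1000) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  bb <- apply(terminal, 2, range)
  out <- matrix(NA_real_, n, 2)
  got <- 0
  for (try in seq_len(max_tries)) {
    m <- max(2 * (n - got), 32)
    x <- runif(m, bb[1, 1], bb[2, 1])
    y <- runif(m, bb[1, 2], bb[2, 2])
    keep <- points_in_polygon(x, y, terminal, boundary = TRUE)
    for (org in organelles) {
      keep <- keep & !points_in_polygon(x, y, org, boundary = TRUE)
    }
    k <- which(keep)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - got))]
      out[(got + 1):(got + length(take)), ] <- cbind(x[take], y[take])
      got <- got + length(take)
    }
    if (got == n) return(out)
  }
  abort("Could not place vesicles: free region too small.")
}

sample_points_near_polyline <- function(n, line, band_nm, terminal,
                                        organelles, max_tries = 1000) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  line <- as.matrix(line)
  seg_len <- sqrt(rowSums(diff(line)^2))
  out <- matrix(NA_real_, n, 2)
  got <- 0
  for (try in seq_len(max_tries)) {
    m <- max(2 * (n - got), 16)
    seg <- sample.int(length(seg_len), m, replace = TRUE, prob = seg_len)
    u <- runif(m)
    px <- line[seg, 1] + u * (line[seg + 1, 1] - line[seg, 1])
    py <- line[seg, 2] + u * (line[seg + 1, 2] - line[seg, 2])
    nx <- -(line[seg + 1, 2] - line[seg, 2]) / seg_len[seg]
    ny <- (line[seg + 1, 1] - line[seg, 1]) / seg_len[seg]
    d <- runif(m, 0, band_nm) * sample(c(-1, 1), m, replace = TRUE)
    x <- px + nx * d
    y <- py + ny * d
    keep <- points_in_polygon(x, y, terminal, boundary = TRUE)
    for (org in organelles) {
      keep <- keep & !points_in_polygon(x, y, org, boundary = TRUE)
    }
    k <- which(keep)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - got))]
      out[(got + 1):(got + length(take)), ] <- cbind(x[take], y[take])
      got <- got + length(take)
    }
    if (got == n) return(out)
  }
  abort("Could not place enrichment vesicles near the active zone.")
}

rtruncnorm_floor <- function(n, mean, sd, floor = 10) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(max(mean, floor), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x > floor])
  }
  out[seq_len(n)]
}
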