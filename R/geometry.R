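## Geometry: rolling a 2D dipole lattice into a helical cylinder.

#' Specify the two-dimensional molecular sheet
#'
#' The sheet is a Bravais lattice of dipole-carrying sites.  `a1` is the
#' stacking direction (for chlorosome-like aggregates the syn-anti stack
#' axis); `a2` the second lattice vector at angle `gamma` from `a1`.  Each
#' site carries a unit transition dipole whose in-sheet projection makes
#' angle `dipole_in_sheet_angle` with `a1` and which is tilted out of the
#' sheet plane by `dipole_out_of_sheet_angle`.
#'
#' @param a1_length,a2_length lattice constants in Angstrom (> 0).
#' @param gamma angle between the lattice vectors in degrees, in (0, 180).
#' @param dipole_in_sheet_angle angle (deg) of the in-sheet dipole
#'   projection, measured from `a1`.
#' @param dipole_out_of_sheet_angle tilt (deg) of the dipole out of the
#'   sheet plane.
#' @return an object of class `lattice_spec`.
#' @export
lattice_spec <- function(a1_length, a2_length, gamma = 90,
                         dipole_in_sheet_angle = 0,
                         dipole_out_of_sheet_angle = 0) {
  stopifnot(is.numeric(a1_length), a1_length > 0,
            is.numeric(a2_length), a2_length > 0,
            gamma > 0, gamma < 180)
  structure(list(a1_length = a1_length, a2_length = a2_length,
                 gamma = gamma,
                 dipole_in_sheet_angle = dipole_in_sheet_angle,
                 dipole_out_of_sheet_angle = dipole_out_of_sheet_angle),
            class = "lattice_spec")
}

#' Specify a cylinder rolled from a sheet
#'
#' The cylinder is defined by the sheet, the chiral angle `delta` (the
#' direction in the sheet that is wrapped around the circumference), the
#' target radius, and the length.  The realized rolling direction is the
#' lattice (chiral) vector closest in direction to `delta` with a length
#' close to the target circumference, so that the rolled lattice closes
#' seamlessly; the radius is re-derived from that vector.
#'
#' @param lattice a [lattice_spec()].
#' @param delta chiral angle in degrees, in `[0, 180)`.
#' @param radius target cylinder radius in Angstrom (> 0).
#' @param length cylinder length in Angstrom (> 0).
#' @param jitter_sd standard deviation (deg) of independent Gaussian
#'   orientational noise added to each molecule's dipole angles,
#'   emulating molecular-scale structural disorder.  0 disables it.
#' @param seed integer seed for the jitter (required when `jitter_sd > 0`).
#' @return an object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(lattice, delta, radius, length,
                          jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(lattice, "lattice_spec"),
            delta >= 0, delta < 180, radius > 0, length > 0,
            jitter_sd >= 0)
  if (jitter_sd > 0 && is.null(seed))
    stop("a seed is required when jitter_sd > 0")
  structure(list(lattice = lattice, delta = delta, radius = radius,
                 length = length, jitter_sd = jitter_sd, seed = seed),
            class = "cylinder_spec")
}

## Lattice basis vectors in sheet Cartesian coordinates (a1 along +x).
lattice_basis <- function(lat) {
  g <- lat$gamma * pi / 180
  rbind(a1 = c(lat$a1_length, 0),
        a2 = c(lat$a2_length * cos(g), lat$a2_length * sin(g)))
}

## Pick the integer chiral vector p*a1 + q*a2 whose direction is closest
## to delta, with length within len_tol of the target circumference.
chiral_vector <- function(lat, delta, radius, len_tol = 0.3) {
  B <- lattice_basis(lat)
  circ <- 2 * pi * radius
  kmax <- max(4L, ceiling(circ * (1 + len_tol) /
                            min(lat$a1_length, lat$a2_length * sin(lat$gamma * pi / 180))) + 1L)
  pq <- as.matrix(expand.grid(p = -kmax:kmax, q = -kmax:kmax))
  vec <- pq %*% B
  len <- sqrt(rowSums(vec^2))
  ang <- atan2(vec[, 2], vec[, 1]) * 180 / pi
  ang <- ang %% 180                      # rolling direction is sign-free
  dang <- abs(ang - delta)
  dang <- pmin(dang, 180 - dang)
  ok <- len > 0 & abs(len - circ) / circ <= len_tol
  if (!any(ok))
    stop("radius too small to host one circumferential lattice repeat; ",
         "increase `radius` (need roughly 2*pi*radius >= ",
         signif(min(lat$a1_length, lat$a2_length), 3), " Angstrom)")
  cand <- which(ok)
  best <- cand[order(dang[cand], abs(len[cand] - circ))][1]
  if (dang[best] > 5)
    stop("no lattice direction within 5 degrees of delta = ", delta,
         " at this radius; try a different radius")
  # orient the chiral vector into the half-plane matching delta
  v <- vec[best, ]
  a <- atan2(v[2], v[1]) * 180 / pi
  if (abs(((a - delta + 90) %% 180) - 90) > 45) v <- -v
  list(vec = v, length = len[best],
       delta_actual = (atan2(v[2], v[1]) * 180 / pi) %% 180)
}

#' Build a cylindrical aggregate by rolling the sheet
#'
#' Sites are the sheet lattice points inside one circumferential strip,
#' mapped onto the cylinder surface (axis along z).  Sheet dipoles are
#' carried along by the local tangent frame: the in-sheet component along
#' the rolling direction becomes azimuthal, the component along the
#' cylinder axis stays axial, and the out-of-sheet component becomes
#' radial.
#'
#' @param spec a [cylinder_spec()].
#' @param dipole_magnitude transition-dipole magnitude in debye.
#' @return an object of class `aggregate` with fields `positions` (N x 3,
#'   Angstrom), `dipoles` (N x 3 unit vectors), `dipole_magnitude`,
#'   `molecule_ids`, `radius` (the realized radius) and `delta_actual`
#'   (the realized chiral angle, deg).
#' @export
build_cylinder <- function(spec, dipole_magnitude = DIPOLE_MAGNITUDE_D) {
  stopifnot(inherits(spec, "cylinder_spec"))
  lat <- spec$lattice
  ch <- chiral_vector(lat, spec$delta, spec$radius)
  L <- spec$length
  cvec <- ch$vec
  clen <- ch$length
  chat <- cvec / clen                      # rolling direction in the sheet
  zhat2 <- c(-chat[2], chat[1])            # axial direction in the sheet

  B <- lattice_basis(lat)
  ## enumerate (i, j) covering the strip u in [0, clen), v in [0, L)
  corners <- rbind(c(0, 0), c(clen, 0), c(0, L), c(clen, L))
  ## sheet coords of strip corners: x = u*chat + v*zhat2
  xy <- corners[, 1] %o% chat + corners[, 2] %o% zhat2
  ij <- xy %*% solve(B)                    # row * B = xy  =>  ij = xy B^-1
  ir <- floor(min(ij[, 1]) - 2):ceiling(max(ij[, 1]) + 2)
  jr <- floor(min(ij[, 2]) - 2):ceiling(max(ij[, 2]) + 2)
  grid <- as.matrix(expand.grid(i = ir, j = jr))
  pts <- grid %*% B
  u <- pts %*% chat
  v <- pts %*% zhat2
  eps <- 1e-9
  keep <- u >= -eps & u < clen - eps & v >= -eps & v < L - eps
  if (sum(keep) < 2)
    stop("cylinder specification yields fewer than 2 molecules; ",
         "increase `length` or `radius`")
  u <- u[keep]; v <- v[keep]
  ord <- order(v, u)
  u <- u[ord]; v <- v[ord]
  n <- length(u)

  radius <- clen / (2 * pi)
  theta <- 2 * pi * u / clen
  pos <- cbind(radius * cos(theta), radius * sin(theta), v)

  ## dipole angles, with optional per-molecule orientational jitter
  alpha <- rep(lat$dipole_in_sheet_angle, n)
  tilt <- rep(lat$dipole_out_of_sheet_angle, n)
  if (spec$jitter_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(spec$seed)
    alpha <- alpha + rnorm(n, 0, spec$jitter_sd)
    tilt <- tilt + rnorm(n, 0, spec$jitter_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  a <- alpha * pi / 180; tl <- tilt * pi / 180
  ## in-sheet dipole direction decomposed along (chat, zhat2)
  dang <- a - atan2(chat[2], chat[1])      # angle from the rolling direction
  comp_u <- cos(tl) * cos(dang)
  comp_z <- cos(tl) * sin(dang)
  comp_r <- sin(tl)
  dip <- cbind(-comp_u * sin(theta) + comp_r * cos(theta),
               comp_u * cos(theta) + comp_r * sin(theta),
               comp_z)

  structure(list(positions = pos, dipoles = dip,
                 dipole_magnitude = dipole_magnitude,
                 molecule_ids = seq_len(n),
                 radius = radius, delta_actual = ch$delta_actual,
                 spec = spec),
            class = "aggregate")
}

#' @export
print.aggregate <- function(x, ...) {
  cat("<aggregate> ", nrow(x$positions), " molecules, radius ",
      signif(x$radius, 4), " A, chiral angle ",
      signif(x$delta_actual, 4), " deg\n", sep = "")
  invisible(x)
}

#' Angles between molecular dipoles and the cylinder axis
#'
#' beta_i = arccos(|mu_i . z|), folded to `[0, 90]` degrees because the
#' transition dipole is sign-ambiguous.
#'
#' @param agg an [build_cylinder()] aggregate.
#' @return numeric vector of angles in degrees.
#' @export
beta_angles <- function(agg) {
  stopifnot(inherits(agg, "aggregate"), nrow(agg$dipoles) >= 1)
  nrm <- sqrt(rowSums(agg$dipoles^2))
  if (any(nrm < 1e-12)) stop("zero-length dipole vector")
  acos(pmin(1, abs(agg$dipoles[, 3] / nrm))) * 180 / pi
}

#' Summarize a beta-angle distribution
#'
#' Arithmetic mean, population standard deviation and a binned histogram
#' of the folded angles.
#'
#' @param betas numeric vector of angles in degrees (length >= 2).
#' @param bin_width histogram bin width in degrees.
#' @return an object of class `beta_summary` with fields `mean_beta`,
#'   `sigma_beta` and `histogram`.
#' @export
summarize_beta <- function(betas, bin_width = 2) {
  if (length(betas) < 2) stop("need at least 2 angles")
  stopifnot(all(is.finite(betas)))
  m <- mean(betas)
  s <- sqrt(mean((betas - m)^2)) # population sd
  breaks <- seq(0, 90 + bin_width, by = bin_width)
  counts <- table(cut(pmin(betas, 90), breaks, right = FALSE))
  structure(list(mean_beta = m, sigma_beta = s,
                 histogram = setNames(as.integer(counts),
                                      head(breaks, -1))),
            class = "beta_summary")
}

#' @export
print.beta_summary <- function(x, ...) {
  cat(sprintf("<beta_summary> mean %.1f deg, sigma %.1f deg\n",
              x$mean_beta, x$sigma_beta))
  invisible(x)
}

#' Preset cylinder specifications
#'
#' Two helicities bracketing the structures discussed for chlorosomal
#' aggregates, plus a small disorder-free cylinder for Bloch-state
#' diagnostics:
#' * `"system1-like"`: chiral angle 49.6 deg, dipoles nearly aligned with
#'   the cylinder axis (mean beta ~ 18 deg, spread ~ 7 deg).
#' * `"system2-like"`: chiral angle 112.3 deg, dipoles near the magic
#'   angle (mean beta ~ 54 deg, spread ~ 5 deg).
#' * `"homogeneous-test"`: achiral, jitter-free rings for selection-rule
#'   checks.
#'
#' The lattice constants are calibrated surrogates, chosen so that the
#' rolled beta statistics match the targets above and, for
#' `"system2-like"`, so that the parallel and perpendicular optical
#' components overlap spectrally (the defining feature of that
#' helicity); they are not derived from an atomistic unit cell.
#'
#' @param name preset name.
#' @param n_molecules approximate number of molecules (sets the cylinder
#'   length).
#' @param seed seed for the orientational jitter.
#' @return a [cylinder_spec()].
#' @export
preset_cylinder <- function(name, n_molecules = 60, seed = 1L) {
  presets <- c("system1-like", "system2-like", "homogeneous-test")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; valid presets: ",
         paste(presets, collapse = ", "))
  len <- function(n, a1, a2, gamma, radius)
    max(10, n * a1 * a2 * sin(gamma * pi / 180) / (2 * pi * radius))
  switch(name,
    "system1-like" = cylinder_spec(
      lattice = lattice_spec(6.8, 9.0, 90, dipole_in_sheet_angle = 120.3),
      delta = 49.6, radius = 9.6,
      length = len(n_molecules, 6.8, 9.0, 90, 9.6),
      jitter_sd = 8, seed = seed),
    "system2-like" = cylinder_spec(
      lattice = lattice_spec(7.7, 7.5, 60, dipole_in_sheet_angle = 148.3),
      delta = 112.3, radius = 10.6,
      length = len(n_molecules, 7.7, 7.5, 60, 10.6),
      jitter_sd = 5, seed = seed),
    "homogeneous-test" = cylinder_spec(
      lattice = lattice_spec(6.8, 9.0, 90, dipole_in_sheet_angle = 35),
      delta = 0, radius = 9.6,
      length = len(n_molecules, 6.8, 9.0, 90, 9.6)))
}

#' Write an aggregate as delimited text
#'
#' One row per molecule: id, x, y, z (Angstrom), and the unit dipole
#' vector.  Header lines prefixed with `#` carry the construction
#' parameters.
#'
#' @param agg an aggregate.
#' @param path output file.
#' @export
write_geometry <- function(agg, path) {
  stopifnot(inherits(agg, "aggregate"))
  hdr <- c(
    sprintf("# excitube geometry: %d molecules", nrow(agg$positions)),
    sprintf("# radius_A %.8g", agg$radius),
    sprintf("# delta_actual_deg %.8g", agg$delta_actual),
    sprintf("# dipole_magnitude_D %.8g", agg$dipole_magnitude),
    "# columns: id x y z mux muy muz")
  df <- data.frame(id = agg$molecule_ids,
                   agg$positions, agg$dipoles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 12, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an aggregate written by [write_geometry()]
#' @param path input file.
#' @return an `aggregate` (without the originating spec).
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getnum <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) return(NA_real_)
    as.numeric(sub(paste0("^# ", key, " "), "", ln[1]))
  }
  df <- read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  if (ncol(df) != 7) stop("malformed geometry file: expected 7 columns")
  structure(list(positions = as.matrix(df[, 2:4]),
                 dipoles = as.matrix(df[, 5:7]),
                 dipole_magnitude = getnum("dipole_magnitude_D"),
                 molecule_ids = as.integer(df[, 1]),
                 radius = getnum("radius_A"),
                 delta_actual = getnum("delta_actual_deg"),
                 spec = NULL),
            class = "aggregate")
}
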