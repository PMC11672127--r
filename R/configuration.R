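# Molecular configurations: element symbols + n x 3 Cartesian coordinates (A),
# with optional per-atom molecule labels.

#' Covalent radii table
#'
#' Single-bond covalent radii (in Angstrom) used for distance-based bond
#' perception and for validating element symbols. Values follow the standard
#' Cordero compilation, except hydrogen, which uses the older Slater-type
#' value of 0.37 A so that the H2 bond (0.741 A) sits comfortably inside the
#' detection band `scale * (R_i + R_j)` for scales down to 1.05. The model
#' elements `A` and `X` (used by the toy reactive surfaces) carry a nominal
#' radius of 0.75 A.
#'
#' @return A data frame with columns `symbol` and `radius`.
#' @export
covalent_radii <- function() {
  data.frame(
    symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
               "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
               "Br", "I", "A", "X"),
    radius = c(0.37, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
               1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
               1.20, 1.39, 0.75, 0.75),
    stringsAsFactors = FALSE
  )
}

.radius_of <- function(symbols) {
  tab <- covalent_radii()
  r <- tab$radius[match(symbols, tab$symbol)]
  if (anyNA(r)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r
}

#' Construct a molecular configuration
#'
#' @param symbols Character vector of element symbols (must be present in
#'   [covalent_radii()]).
#' @param coords Numeric n x 3 matrix of Cartesian coordinates in Angstrom.
#' @param molecule_id Optional integer vector labelling which molecule each
#'   atom belongs to. When present it must cover every atom.
#' @return An object of class `rtip_config`.
#' @export
configuration <- function(symbols, coords, molecule_id = NULL) {
  symbols <- as.character(symbols)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(symbols) < 1L) {
    stop("configuration must contain at least one atom", call. = FALSE)
  }
  if (!is.matrix(coords) || ncol(coords) != 3L || nrow(coords) != length(symbols)) {
    stop("coords must be an n x 3 matrix matching length(symbols)", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  .radius_of(symbols)  # validates symbols
  if (!is.null(molecule_id)) {
    molecule_id <- as.integer(molecule_id)
    if (length(molecule_id) != length(symbols) || anyNA(molecule_id)) {
      stop("molecule_id must label every atom", call. = FALSE)
    }
  }
  dimnames(coords) <- NULL
  structure(list(symbols = symbols, coords = coords, molecule_id = molecule_id),
            class = "rtip_config")
}

#' @export
print.rtip_config <- function(x, ...) {
  cat(sprintf("<rtip_config> %d atoms (%s)%s\n",
              n_atoms(x), paste(unique(x$symbols), collapse = ","),
              if (is.null(x$molecule_id)) ""
              else sprintf(", %d molecule(s)", length(unique(x$molecule_id)))))
  invisible(x)
}

#' Number of atoms in a configuration
#' @param config An `rtip_config`.
#' @return Integer atom count.
#' @export
n_atoms <- function(config) nrow(config$coords)

#' Centroid of a configuration
#' @param config An `rtip_config`.
#' @return Length-3 numeric vector (A).
#' @export
centroid <- function(config) colMeans(config$coords)

#' Centre a configuration on its centroid
#'
#' @param config An `rtip_config`.
#' @return A list with elements `config` (the centred configuration) and
#'   `centroid` (the removed centroid, A). Adding the centroid back
#'   reconstructs the input exactly.
#' @export
center_configuration <- function(config) {
  stopifnot(inherits(config, "rtip_config"))
  c0 <- centroid(config)
  out <- config
  out$coords <- sweep(config$coords, 2L, c0)
  list(config = out, centroid = c0)
}

#' Construct a rigid motion
#'
#' A proper rigid motion `p -> R p + t`. In homogeneous coordinates
#' `(x, y, z, 1)` it is the 4 x 4 matrix with block structure
#' `[R t; 0 0 0 1]` (see [as_homogeneous()]).
#'
#' @param rotation 3 x 3 orthogonal matrix with determinant +1 (to 1e-10).
#' @param translation Length-3 numeric vector (A).
#' @return An object of class `rtip_rigid_motion`.
#' @export
rigid_motion <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10 ||
      abs(det(rotation) - 1) > 1e-10) {
    stop("rotation must be orthogonal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rtip_rigid_motion")
}

#' Homogeneous 4 x 4 form of a rigid motion
#' @param motion An `rtip_rigid_motion`.
#' @return A 4 x 4 matrix whose last row is (0, 0, 0, 1).
#' @export
as_homogeneous <- function(motion) {
  stopifnot(inherits(motion, "rtip_rigid_motion"))
  rbind(cbind(motion$rotation, motion$translation), c(0, 0, 0, 1))
}

#' Apply a rigid motion to a configuration
#' @param config An `rtip_config`.
#' @param motion An `rtip_rigid_motion`.
#' @return The transformed configuration.
#' @export
apply_rigid_motion <- function(config, motion) {
  stopifnot(inherits(config, "rtip_config"), inherits(motion, "rtip_rigid_motion"))
  out <- config
  out$coords <- config$coords %*% t(motion$rotation) +
    matrix(motion$translation, n_atoms(config), 3L, byrow = TRUE)
  out
}

# rotation matrix from a unit quaternion (q0, q1, q2, q3)
.quat_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  q0 <- q[1L]; q1 <- q[2L]; q2 <- q[3L]; q3 <- q[4L]
  matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2
  ), 3L, 3L, byrow = TRUE)
}

#' Draw a uniformly distributed random rotation
#'
#' Uniform over SO(3) via a normalised 4-variate Gaussian quaternion.
#' Uses the current RNG state.
#' @return A 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  .quat_to_rotation(stats::rnorm(4L))
}

# evaluate `code` under a temporary seed, restoring RNG state afterwards
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
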