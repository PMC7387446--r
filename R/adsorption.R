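#' Random site-occupancy field
#'
#' The null model for second-layer adsorption: every site of an nx x ny
#' square lattice is occupied independently with probability `theta` (no
#' energetic bias towards occupied neighbours).
#'
#' @param n_x,n_y Lattice dimensions (>= 1).
#' @param theta Occupation probability in [0, 1].
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @param neighborhood 4 (von Neumann, default: matches lateral
#'   bonding to up to four neighbours) or 8 (Moore).
#' @param periodic Toroidal boundaries? Default `FALSE` (edge sites count
#'   only their existing neighbours).
#' @return An `occupancy_field`: logical matrix with attributes
#'   `neighborhood`, `periodic`, `theta`.
#' @export
#' @examples
#' f <- random_occupancy(50, 50, 0.23, seed = 1)
#' mean(f)  # realized coverage near 0.23
random_occupancy <- function(n_x, n_y, theta, seed = NULL,
                             neighborhood = 4L, periodic = FALSE) {
  if (!is.finite(theta) || theta < 0 || theta > 1)
    stop("theta must lie in [0, 1]", call. = FALSE)
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (n_x < 1L || n_y < 1L) stop("lattice dimensions must be >= 1",
                                 call. = FALSE)
  if (!neighborhood %in% c(4L, 8L))
    stop("neighborhood must be 4 (von Neumann) or 8 (Moore)", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  occ <- matrix(stats::runif(n_x * n_y) < theta, n_x, n_y)
  structure(occ, class = c("occupancy_field", "matrix"),
            neighborhood = as.integer(neighborhood),
            periodic = periodic, theta = theta)
}

# shift a matrix by (di, dj); non-periodic shifts pad with FALSE
.shift <- function(m, di, dj, periodic) {
  n_x <- nrow(m); n_y <- ncol(m)
  if (periodic) {
    ri <- ((seq_len(n_x) - 1L - di) %% n_x) + 1L
    rj <- ((seq_len(n_y) - 1L - dj) %% n_y) + 1L
    m[ri, rj, drop = FALSE]
  } else {
    out <- matrix(FALSE, n_x, n_y)
    si <- seq_len(n_x) - di; sj <- seq_len(n_y) - dj
    oki <- si >= 1L & si <= n_x; okj <- sj >= 1L & sj <= n_y
    out[oki, okj] <- m[si[oki], sj[okj], drop = FALSE]
    out
  }
}

.neighbor_offsets <- function(neighborhood) {
  vn <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (neighborhood == 4L) vn else
    rbind(vn, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
}

#' Fraction of sites holding isolated monomers
#'
#' The fraction of all lattice sites that are occupied and have zero
#' occupied neighbours. With non-periodic boundaries only existing
#' neighbours are counted.
#'
#' @param field An [random_occupancy()] field (or any logical matrix; then
#'   `neighborhood`/`periodic` must be supplied).
#' @param neighborhood,periodic Overrides for plain matrices.
#' @return Isolated-monomer coverage (fraction of all sites).
#' @export
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' isolated_coverage(structure(m, class = c("occupancy_field", "matrix"),
#'                             neighborhood = 4L, periodic = FALSE))  # 1/25
isolated_coverage <- function(field, neighborhood = NULL, periodic = NULL) {
  nb <- neighborhood %||% attr(field, "neighborhood") %||% 4L
  per <- periodic %||% attr(field, "periodic") %||% FALSE
  m <- unclass(field)
  attributes(m) <- list(dim = dim(field))
  storage.mode(m) <- "logical"
  nn <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(nrow(.neighbor_offsets(nb)))) {
    off <- .neighbor_offsets(nb)[k, ]
    nn <- nn + .shift(m, off[1], off[2], per)
  }
  sum(m & nn == 0L) / length(m)
}

#' Expected isolated coverage under independent occupancy
#'
#' Closed form for a site with z independent neighbours:
#' theta (1 - theta)^z. On a toroidal lattice every site has z neighbours
#' exactly; with free edges the interior value is an upper bound on the
#' edge contribution's complement.
#'
#' @param theta Coverage fraction.
#' @param z Neighbourhood size (4 = von Neumann, 8 = Moore).
#' @return Expected isolated-monomer coverage.
#' @export
#' @examples
#' isolated_coverage_expected(0.23)  # 0.0808 for von Neumann
isolated_coverage_expected <- function(theta, z = 4L) {
  if (any(theta < 0) || any(theta > 1)) stop("theta must lie in [0, 1]",
                                             call. = FALSE)
  theta * (1 - theta)^z
}

#' Expected-to-observed isolation ratio
#'
#' @param expected Expected isolated coverage under the random null.
#' @param observed Observed isolated coverage (> 0).
#' @return The fold ratio expected / observed; values well above 1 indicate
#'   cooperative (bond-mediated) attachment suppressing isolated monomers.
#' @export
#' @examples
#' isolation_ratio(0.07, 0.0035)  # 20
isolation_ratio <- function(expected, observed) {
  if (any(!is.finite(observed)) || any(observed <= 0))
    stop("observed coverage must be > 0", call. = FALSE)
  expected / observed
}

#' Monte Carlo summary of the adsorption null model
#'
#' Simulates `reps` independent occupancy fields and summarizes the
#' isolated-monomer coverage against the closed form and, optionally, an
#' observed value.
#'
#' @param theta Coverage fraction.
#' @param n Linear lattice size (n x n).
#' @param reps Number of replicate fields.
#' @param seed Integer seed.
#' @param neighborhood 4 or 8.
#' @param periodic Toroidal boundaries?
#' @param observed Optional observed isolated coverage for the ratio.
#' @return data.frame (one row) with `theta`, `expected_closed_form`,
#'   `simulated_mean`, `simulated_se`, and `ratio_expected_to_observed`
#'   (NA when no observation given).
#' @export
#' @examples
#' adsorption_summary(0.23, n = 60, reps = 20, seed = 7, observed = 0.0035)
adsorption_summary <- function(theta, n = 200L, reps = 100L, seed = 1L,
                               neighborhood = 4L, periodic = FALSE,
                               observed = NULL) {
  iso <- vapply(seq_len(reps), function(k) {
    isolated_coverage(random_occupancy(n, n, theta, seed = seed + k - 1L,
                                       neighborhood = neighborhood,
                                       periodic = periodic))
  }, numeric(1))
  expected <- isolated_coverage_expected(theta, neighborhood)
  data.frame(
    theta = theta,
    expected_closed_form = expected,
    simulated_mean = mean(iso),
    simulated_se = stats::sd(iso) / sqrt(reps),
    ratio_expected_to_observed =
      if (is.null(observed)) NA_real_ else isolation_ratio(expected, observed)
  )
}
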