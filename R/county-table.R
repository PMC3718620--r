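#' County structure: identifiers, adjacency, covariates, race populations
#'
#' A `county_table` bundles everything the small-area models need to know
#' about counties: the set of county identifiers, a symmetric adjacency
#' structure (used by the geospatial term), per-year county covariates, and
#' race-specific population counts (used for poststratification).
#'
#' @param county_ids character vector of unique county identifiers.
#' @param neighbors named list mapping each county id to a character vector of
#'   adjacent county ids. Adjacency must be symmetric and irreflexive.
#' @param covariates `data.frame` with columns `county_id`, `year`, and the
#'   columns in [county_covariates], or `NULL` if not yet populated.
#' @param race_populations `data.frame` with columns `county_id`, `race`,
#'   `population` (one row per county x race), or `NULL`.
#'
#' @return An object of class `county_table`.
#' @seealso [make_county_grid()], [populate_county_data()]
#' @export
county_table <- function(county_ids, neighbors, covariates = NULL,
                         race_populations = NULL) {
  county_ids <- as.character(county_ids)
  if (anyDuplicated(county_ids)) stop("duplicated county ids")
  if (!setequal(names(neighbors), county_ids))
    stop("'neighbors' must be a named list covering exactly the county ids")
  neighbors <- lapply(neighbors[county_ids], as.character)
  for (id in county_ids) {
    nb <- neighbors[[id]]
    if (id %in% nb) stop("county ", id, " listed as its own neighbor")
    if (!all(nb %in% county_ids))
      stop("unknown neighbor id(s) for county ", id)
    for (j in nb) if (!(id %in% neighbors[[j]]))
      stop("adjacency not symmetric: ", id, " -> ", j)
  }
  if (!is.null(covariates)) {
    need <- c("county_id", "year")
    miss <- setdiff(need, names(covariates))
    if (length(miss)) stop("covariates missing column(s): ",
                           paste(miss, collapse = ", "))
    if (!all(covariates$county_id %in% county_ids))
      stop("covariates contain unknown county ids")
    for (v in intersect(c("poverty", "unemployment", "pct_rural",
                          "pct_hs_diploma"), names(covariates))) {
      x <- covariates[[v]]
      if (any(!is.na(x) & (x < 0 | x > 1)))
        stop("covariate '", v, "' must lie in [0, 1]")
    }
  }
  if (!is.null(race_populations)) {
    need <- c("county_id", "race", "population")
    miss <- setdiff(need, names(race_populations))
    if (length(miss)) stop("race_populations missing column(s): ",
                           paste(miss, collapse = ", "))
    if (!all(race_populations$race %in% race_groups))
      stop("unknown race level(s): ",
           paste(setdiff(race_populations$race, race_groups), collapse = ", "))
    if (any(race_populations$population < 0))
      stop("race populations must be non-negative")
    tot <- tapply(race_populations$population, race_populations$county_id, sum)
    if (any(tot <= 0)) stop("every county must have total population > 0")
  }
  structure(list(county_ids = county_ids, neighbors = neighbors,
                 covariates = covariates,
                 race_populations = race_populations),
            class = "county_table")
}

#' @export
print.county_table <- function(x, ...) {
  cat("county_table:", length(x$county_ids), "counties,",
      sum(lengths(x$neighbors)) / 2, "adjacency edges\n")
  cat("  covariates:",
      if (is.null(x$covariates)) "<empty>" else
        paste(length(unique(x$covariates$year)), "year(s)"), "\n")
  cat("  race populations:",
      if (is.null(x$race_populations)) "<empty>" else "present", "\n")
  invisible(x)
}

n_counties <- function(counties) length(counties$county_ids)

#' Rectangular lattice of counties with rook adjacency
#'
#' Builds a `rows x cols` grid of synthetic counties where edge-sharing cells
#' are neighbors — a stand-in for a real county adjacency map. Covariates and
#' populations start empty; see [populate_county_data()].
#'
#' @param rows,cols positive grid dimensions.
#' @return A [county_table()] with `rows * cols` counties.
#' @examples
#' g <- make_county_grid(3, 3)
#' lengths(g$neighbors)  # corners 2, edges 3, center 4
#' @export
make_county_grid <- function(rows, cols) {
  if (!is.numeric(rows) || !is.numeric(cols) || length(rows) != 1L ||
      length(cols) != 1L || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols))
    stop("'rows' and 'cols' must be positive integers")
  rows <- as.integer(rows); cols <- as.integer(cols)
  idx <- function(r, c) sprintf("c%04d", (r - 1L) * cols + c)
  ids <- character(rows * cols)
  nbrs <- vector("list", rows * cols)
  k <- 0L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    k <- k + 1L
    ids[k] <- idx(r, c)
    nb <- character(0)
    if (r > 1L)   nb <- c(nb, idx(r - 1L, c))
    if (r < rows) nb <- c(nb, idx(r + 1L, c))
    if (c > 1L)   nb <- c(nb, idx(r, c - 1L))
    if (c < cols) nb <- c(nb, idx(r, c + 1L))
    nbrs[[k]] <- nb
  }
  names(nbrs) <- ids
  county_table(ids, nbrs)
}

#' Fill a county table with synthetic covariates and race populations
#'
#' Draws per-county covariate levels (with a small linear drift over years)
#' and race-specific populations, giving the generator realistic between-
#' county heterogeneity: poverty and unemployment on plausible proportion
#' ranges, percent rural spanning the unit interval, a high-school-diploma
#' share, a PM2.5-like pollution level, and a doctors/dentists rate per
#' 100,000 population. Race composition is drawn from a Dirichlet centred on
#' a white-majority mix.
#'
#' @param counties a [county_table()].
#' @param years integer vector of calendar years to cover.
#' @param seed integer seed; output is fully determined by it.
#' @return The `county_table` with `covariates` and `race_populations` filled.
#' @export
populate_county_data <- function(counties, years, seed = 1L) {
  stopifnot(inherits(counties, "county_table"), length(years) >= 1)
  years <- sort(as.integer(years))
  ids <- counties$county_ids
  C <- length(ids)
  with_seed(child_seed(seed, "county-data"), {
    base <- data.frame(
      county_id = ids,
      poverty = stats::plogis(stats::rnorm(C, -1.8, 0.5)),
      unemployment = stats::plogis(stats::rnorm(C, -2.6, 0.35)),
      pct_rural = stats::runif(C),
      pct_hs_diploma = stats::plogis(stats::rnorm(C, 1.4, 0.4)),
      pm25 = exp(stats::rnorm(C, log(10), 0.3)),
      docs_per_100k = stats::rgamma(C, shape = 8, rate = 8 / 200))
    drift <- data.frame(
      poverty = stats::rnorm(C, 0, 0.003),
      unemployment = stats::rnorm(C, 0, 0.002),
      docs_per_100k = stats::rnorm(C, 0, 2))
    cov <- do.call(rbind, lapply(seq_along(years), function(i) {
      d <- base
      d$year <- years[i]
      t <- i - 1L
      d$poverty <- pmin(pmax(d$poverty + t * drift$poverty, 0.01), 0.6)
      d$unemployment <- pmin(pmax(d$unemployment + t * drift$unemployment,
                                  0.005), 0.4)
      d$docs_per_100k <- pmax(d$docs_per_100k + t * drift$docs_per_100k, 5)
      d
    }))
    rownames(cov) <- NULL
    # Dirichlet via normalized gammas, centred on a white-majority mix
    alpha <- c(white = 14, black = 3, hispanic = 3, native_american = 0.5,
               other = 1.5)
    g <- matrix(stats::rgamma(C * length(alpha),
                              shape = rep(alpha, each = C)), nrow = C)
    shares <- g / rowSums(g)
    total <- round(exp(stats::rnorm(C, log(30000), 0.8)))
    pops <- data.frame(
      county_id = rep(ids, times = length(race_groups)),
      race = rep(race_groups, each = C),
      population = pmax(round(as.vector(shares) * total), 1))
    county_table(ids, counties$neighbors, covariates = cov,
                 race_populations = pops)
  })
}

# race shares per county as a counties x races matrix (rows sum to 1)
race_share_matrix <- function(counties) {
  rp <- counties$race_populations
  if (is.null(rp)) stop("county table has no race populations")
  m <- matrix(0, n_counties(counties), length(race_groups),
              dimnames = list(counties$county_ids, race_groups))
  m[cbind(match(rp$county_id, counties$county_ids),
          match(rp$race, race_groups))] <- rp$population
  m / rowSums(m)
}

county_total_population <- function(counties) {
  rp <- counties$race_populations
  if (is.null(rp)) stop("county table has no race populations")
  tot <- tapply(rp$population, rp$county_id, sum)
  as.numeric(tot[counties$county_ids])
}
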