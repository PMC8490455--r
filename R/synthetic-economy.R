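#' Default sector table for toy economies
#'
#' Three stylised sectors: outdoor high-workload primary production (AGR),
#' indoor moderate-workload manufacturing (MAN) and indoor low-workload
#' services (SER).
#'
#' @return data frame with columns `sector`, `workload`, `outdoor`.
#' @export
defaultSectors <- function() {
  data.frame(sector = c("AGR", "MAN", "SER"),
             workload = c("high", "moderate", "low"),
             outdoor = c(TRUE, FALSE, FALSE))
}

#' Configuration of the toy-economy generator
#'
#' @param n_regions number of regions (>= 1).
#' @param n_countries number of countries the regions are grouped into.
#' @param sectors data frame with columns `sector`, `workload` (one of
#'   low/moderate/high) and `outdoor` (logical); at least two sectors with
#'   at least one outdoor and one indoor.
#' @param io_density share of each sector's output cost spent on
#'   intermediate inputs; in \[0, 1).
#' @param trade_openness share of every region's demand that is imported;
#'   in \[0, 1\] (must be 0 for a single region).
#' @param labour_share_range range of the labour share of value added from
#'   which region-sector shares are drawn.
#' @param seed integer seed.
#' @return an object of class `toy_economy_config`.
#' @export
toyEconomyConfig <- function(n_regions = 2L, n_countries = 1L,
                             sectors = defaultSectors(),
                             io_density = 0.3, trade_openness = 0.2,
                             labour_share_range = c(0.45, 0.65),
                             seed = 1L) {
  if (n_regions < 1L) stop("invalid config: n_regions < 1", call. = FALSE)
  if (n_countries < 1L || n_countries > n_regions)
    stop("invalid config: n_countries must be in 1..n_regions",
         call. = FALSE)
  stopifnot(is.data.frame(sectors),
            all(c("sector", "workload", "outdoor") %in% names(sectors)))
  if (nrow(sectors) < 2L || !any(sectors$outdoor) || all(sectors$outdoor))
    stop("invalid config: need >= 2 sectors with at least one outdoor and ",
         "one indoor", call. = FALSE)
  if (!all(sectors$workload %in% workload_classes$label))
    stop("invalid config: unknown workload class", call. = FALSE)
  if (io_density < 0 || io_density >= 1)
    stop("invalid config: io_density must be in [0, 1)", call. = FALSE)
  if (trade_openness < 0 || trade_openness > 1)
    stop("invalid config: trade_openness must be in [0, 1]", call. = FALSE)
  if (n_regions == 1L && trade_openness > 0)
    stop("invalid config: a single region cannot trade", call. = FALSE)
  structure(list(n_regions = as.integer(n_regions),
                 n_countries = as.integer(n_countries), sectors = sectors,
                 io_density = io_density, trade_openness = trade_openness,
                 labour_share_range = labour_share_range,
                 seed = as.integer(seed)),
            class = "toy_economy_config")
}

#' Generate a balanced toy multi-region economy
#'
#' Constructs a social accounting matrix that is balanced by construction.
#' Technology (intermediate-use coefficients summing to `io_density` per
#' sector), household expenditure shares and factor splits are drawn first;
#' market-clearing gross outputs are then obtained as the Perron
#' eigenvector of the induced demand-circulation matrix, whose columns sum
#' to one in value, so every account's receipts equal its expenditures up
#' to linear-algebra precision. Sourcing of every use is split between the
#' home region (share 1 - trade_openness) and the other regions (equal
#' shares of trade_openness).
#'
#' @param config a [toyEconomyConfig()].
#' @return an object of class `toy_economy`: list with `regions`,
#'   `sectors`, gross output `X` (regions x sectors, benchmark values at
#'   unit prices), intermediate coefficients `A` (good x sector x region),
#'   consumption shares `theta` (regions x goods), sourcing shares `phi`
#'   (destination x source), factor payments `L_pay`/`K_pay`, the full
#'   `sam` matrix, trade flow array `trade` (source x destination x good)
#'   and the generating `config`.
#' @export
generateToyEconomy <- function(config) {
  stopifnot(inherits(config, "toy_economy_config"))
  R <- config$n_regions; S <- nrow(config$sectors)
  regions <- sprintf("R%02d", seq_len(R))
  country <- sprintf("C%02d",
                     ceiling(seq_len(R) / (R / config$n_countries)))
  sec <- config$sectors$sector
  io <- config$io_density; tr <- config$trade_openness

  drawn <- with_seed(config$seed, {
    A <- array(0, dim = c(S, S, R), dimnames = list(sec, sec, regions))
    for (r in seq_len(R)) for (s in seq_len(S)) {
      g <- rgamma(S, shape = 2)
      A[, s, r] <- io * g / sum(g)
    }
    theta <- matrix(rgamma(R * S, shape = 2), R, S,
                    dimnames = list(regions, sec))
    theta <- theta / rowSums(theta)
    ls <- matrix(runif(R * S, config$labour_share_range[1L],
                       config$labour_share_range[2L]), R, S,
                 dimnames = list(regions, sec))
    list(A = A, theta = theta, ls = ls)
  })
  A <- drawn$A; theta <- drawn$theta

  phi <- matrix(if (R > 1L) tr / (R - 1L) else 0, R, R,
                dimnames = list(regions, regions))
  diag(phi) <- 1 - tr

  # demand circulation over stacked (region, sector) accounts: the value a
  # unit of activity (d, s) sends to supplier (src, g), via intermediates
  # and the recycling of its value added through household consumption
  n <- R * S
  idx <- function(r, s) (r - 1L) * S + s
  B <- matrix(0, n, n)
  for (d in seq_len(R)) for (s in seq_len(S)) {
    va <- 1 - io
    for (g in seq_len(S)) {
      pull <- A[g, s, d] + theta[d, g] * va
      for (src in seq_len(R)) {
        B[idx(src, g), idx(d, s)] <- B[idx(src, g), idx(d, s)] +
          phi[d, src] * pull
      }
    }
  }
  # columns sum to one, so 1 is the Perron eigenvalue; market-clearing
  # outputs are a positive fixed point of the circulation. Power iteration
  # from a uniform start converges within each primitive block (regions
  # decouple under autarky), preserving total value at every step.
  x <- rep(1, n)
  for (it in seq_len(10000L)) {
    x_new <- as.vector(B %*% x)
    if (max(abs(x_new - x)) < 1e-13) { x <- x_new; break }
    x <- x_new
  }
  if (max(abs(as.vector(B %*% x) - x)) > 1e-10 || any(x <= 0))
    stop("invalid config: circulation matrix has no positive fixed point",
         call. = FALSE)
  x <- x * (100 * n) / sum(x)
  X <- matrix(x, R, S, byrow = TRUE, dimnames = list(regions, sec))

  VA <- (1 - io) * X
  L_pay <- drawn$ls * VA
  K_pay <- VA - L_pay
  Y <- rowSums(VA)
  # total absorption of composite good g in destination d
  U <- matrix(0, R, S, dimnames = list(regions, sec))
  for (d in seq_len(R)) for (g in seq_len(S))
    U[d, g] <- sum(A[g, , d] * X[d, ]) + theta[d, g] * Y[d]

  trade <- array(0, dim = c(R, R, S),
                 dimnames = list(src = regions, dest = regions, good = sec))
  for (d in seq_len(R)) for (src in seq_len(R)) for (g in seq_len(S))
    trade[src, d, g] <- phi[d, src] * U[d, g]

  # assemble the SAM: activities, factors and a household per region
  acct <- c(as.vector(t(outer(regions, sec, paste, sep = "."))),
            paste0("LAB.", regions), paste0("CAP.", regions),
            paste0("HH.", regions))
  sam <- matrix(0, length(acct), length(acct),
                dimnames = list(acct, acct))
  act <- function(r, s) paste0(regions[r], ".", sec[s])
  for (d in seq_len(R)) for (s in seq_len(S)) {
    for (g in seq_len(S)) for (src in seq_len(R)) {
      v <- phi[d, src] * A[g, s, d] * X[d, s]
      sam[act(src, g), act(d, s)] <- sam[act(src, g), act(d, s)] + v
    }
    sam[paste0("LAB.", regions[d]), act(d, s)] <- L_pay[d, s]
    sam[paste0("CAP.", regions[d]), act(d, s)] <- K_pay[d, s]
  }
  for (d in seq_len(R)) {
    for (g in seq_len(S)) for (src in seq_len(R)) {
      v <- phi[d, src] * theta[d, g] * Y[d]
      sam[act(src, g), paste0("HH.", regions[d])] <-
        sam[act(src, g), paste0("HH.", regions[d])] + v
    }
    sam[paste0("HH.", regions[d]), paste0("LAB.", regions[d])] <-
      sum(L_pay[d, ])
    sam[paste0("HH.", regions[d]), paste0("CAP.", regions[d])] <-
      sum(K_pay[d, ])
  }

  structure(list(regions = data.frame(region = regions, country = country),
                 sectors = config$sectors, X = X, A = A, theta = theta,
                 phi = phi, L_pay = L_pay, K_pay = K_pay, U = U,
                 trade = trade, sam = sam, config = config),
            class = "toy_economy")
}

#' @export
print.toy_economy <- function(x, ...) {
  cat("<toy_economy> ", nrow(x$regions), " regions x ", nrow(x$sectors),
      " sectors; total output ", signif(sum(x$X), 4),
      "; balance residual ", signif(samBalance(x), 2), "\n", sep = "")
  invisible(x)
}

#' Relative balance residual of a toy economy's SAM
#'
#' @param economy a `toy_economy`.
#' @return max over accounts of |receipts - expenditures| divided by total
#'   SAM turnover.
#' @export
samBalance <- function(economy) {
  stopifnot(inherits(economy, "toy_economy"))
  max(abs(rowSums(economy$sam) - colSums(economy$sam))) / sum(economy$sam)
}

#' Write a toy economy's SAM and metadata as CSV
#'
#' @param economy a `toy_economy`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEconomyCSV <- function(economy, dir) {
  stopifnot(inherits(economy, "toy_economy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(economy$sam, file.path(dir, "sam.csv"))
  write.csv(economy$sectors, file.path(dir, "sectors.csv"),
            row.names = FALSE)
  write.csv(economy$regions, file.path(dir, "regions.csv"),
            row.names = FALSE)
  invisible(dir)
}
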