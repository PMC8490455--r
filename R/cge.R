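# Comparative-static multi-region multi-sector general equilibrium.
#
# Structure: Leontief output technology between an Armington composite of
# every good and CES value added of capital and labour (with factor
# productivities chi, psi); a CES Armington nest between the domestic
# variety and an import composite; a CRESH aggregator over import sources
# with pair-specific elasticities (raised 20% for within-country pairs);
# Cobb-Douglas households owning regionally fixed, fully employed factor
# endowments. All functions are in calibrated-share form so the unshocked
# model replicates the benchmark SAM at unit prices.

#' Calibrate CGE parameters from a toy economy
#'
#' Reads benchmark flows off the balanced SAM (unit-price convention:
#' benchmark quantities equal benchmark values) and attaches the
#' substitution elasticities. Import-sourcing elasticities between regions
#' of the same country are 1.2 times the base value (border effect).
#'
#' @param economy a `toy_economy`.
#' @param elasticities list with `sigma_va` (factor substitution, scalar or
#'   per sector; 1 gives Cobb-Douglas), `sigma_arm` (domestic/import
#'   substitution) and `sigma_imp` (base import-sourcing elasticity; must
#'   exceed 1 whenever more than one import source exists).
#' @return an object of class `cge_params`.
#' @export
calibrateCGE <- function(economy,
                         elasticities = list(sigma_va = 1, sigma_arm = 2,
                                             sigma_imp = 4)) {
  stopifnot(inherits(economy, "toy_economy"))
  if (samBalance(economy) > 1e-6)
    stop("calibration error: SAM is not balanced", call. = FALSE)
  R <- nrow(economy$regions); S <- nrow(economy$sectors)
  regions <- economy$regions$region; sec <- economy$sectors$sector
  sigma_va <- rep_len(elasticities$sigma_va %||% 1, S)
  sigma_arm <- elasticities$sigma_arm %||% 2
  sig_imp_base <- elasticities$sigma_imp %||% 4

  same_country <- outer(economy$regions$country, economy$regions$country,
                        `==`)
  sigma_imp <- matrix(sig_imp_base, R, R,
                      dimnames = list(regions, regions))
  sigma_imp[same_country] <- sig_imp_base * 1.2
  diag(sigma_imp) <- NA_real_

  X0 <- economy$X
  VA0 <- economy$L_pay + economy$K_pay
  thL <- economy$L_pay / VA0
  thK <- economy$K_pay / VA0
  va_coef <- VA0 / X0

  # Armington benchmark: domestic use and imports of good g in region r
  U <- economy$U
  D0 <- U * diag(economy$phi)[row(U)]
  M0 <- U - D0
  thD <- ifelse(U > 0, D0 / U, 1)
  thM <- 1 - thD

  # CRESH calibration per (destination, good): with benchmark source
  # shares x0 (unit prices), k_i = (sigma_i - 1)/sigma_i, lambda0 = sum
  # x0_i/k_i and B_i = x0_i^(1-k_i) / (k_i lambda0)
  cresh <- vector("list", R)
  names(cresh) <- regions
  for (d in seq_len(R)) {
    cresh[[d]] <- vector("list", S)
    names(cresh[[d]]) <- sec
    for (g in seq_len(S)) {
      if (M0[d, g] <= 1e-12) next
      src <- setdiff(seq_len(R), d)
      x0 <- economy$trade[src, d, g] / M0[d, g]
      keep <- x0 > 1e-12
      src <- src[keep]; x0 <- x0[keep]
      sig <- sigma_imp[d, src]
      if (length(src) > 1L && any(sig <= 1))
        stop("calibration error: sigma_imp must exceed 1 for CRESH ",
             "sourcing", call. = FALSE)
      k <- (sig - 1) / sig
      if (length(src) == 1L) k <- max(k, 0.5)  # degenerate, price-neutral
      lam0 <- sum(x0 / k)
      cresh[[d]][[g]] <- list(src = src, x0 = x0, k = k,
                              B = x0^(1 - k) / (k * lam0), lam0 = lam0)
    }
  }

  structure(list(regions = economy$regions, sectors = economy$sectors,
                 R = R, S = S,
                 sigma_va = sigma_va, sigma_arm = sigma_arm,
                 sigma_imp = sigma_imp,
                 X0 = X0, VA0 = VA0, L0 = economy$L_pay, K0 = economy$K_pay,
                 thL = thL, thK = thK, va_coef = va_coef,
                 A = economy$A, theta = economy$theta,
                 D0 = D0, M0 = M0, thD = thD, thM = thM, cresh = cresh,
                 L_r = rowSums(economy$L_pay), K_r = rowSums(economy$K_pay),
                 psi = matrix(1, R, S, dimnames = dimnames(X0)),
                 chi = matrix(1, R, S, dimnames = dimnames(X0))),
            class = "cge_params")
}

#' Apply a labour-productivity shock
#'
#' Scales labour productivity by (1 - tau) in every shocked region-sector;
#' all other parameters are untouched. Sequential shocks compose
#' multiplicatively.
#'
#' @param params a `cge_params`.
#' @param shock a `productivity_shock` (or any data frame with columns
#'   `region`, `sector`, `tau`).
#' @return the shocked `cge_params`.
#' @export
applyShock <- function(params, shock) {
  stopifnot(inherits(params, "cge_params"), is.data.frame(shock),
            all(c("region", "sector", "tau") %in% names(shock)))
  if (any(shock$tau < 0 | shock$tau >= 1))
    stop("invalid input: tau must lie in [0, 1)", call. = FALSE)
  for (i in seq_len(nrow(shock))) {
    r <- as.character(shock$region[i]); s <- as.character(shock$sector[i])
    if (!(r %in% rownames(params$psi)) || !(s %in% colnames(params$psi)))
      stop("invalid input: unknown region-sector in shock: ", r, "/", s,
           call. = FALSE)
    params$psi[r, s] <- params$psi[r, s] * (1 - shock$tau[i])
  }
  params
}

# CRESH source allocation per unit of import composite: solves the scalar
# lambda in sum_i B_i (lambda B_i k_i / p_i)^(k_i/(1-k_i)) = 1, then
# x_i = (lambda B_i k_i / p_i)^(1/(1-k_i)).
#' @noRd
cresh_alloc <- function(cr, p_src) {
  if (length(cr$src) == 1L)
    return(list(x = 1, pm = p_src))
  gfun <- function(lam)
    sum(cr$B * (lam * cr$B * cr$k / p_src)^(cr$k / (1 - cr$k))) - 1
  g0 <- gfun(cr$lam0)
  if (abs(g0) < 1e-14) {
    lam <- cr$lam0
  } else {
    lo <- hi <- cr$lam0
    if (g0 > 0) while (gfun(lo) > 0) lo <- lo / 4
    else while (gfun(hi) < 0) hi <- hi * 4
    lam <- uniroot(gfun, c(lo, hi), tol = 1e-12)$root
  }
  x <- (lam * cr$B * cr$k / p_src)^(1 / (1 - cr$k))
  list(x = x, pm = sum(p_src * x))
}

# Model equations at a candidate price vector. z stacks log output prices
# (R*S), log wages (R) and log capital rents (R). Returns residuals
# (zero-profit in logs; factor-market clearing relative to endowments;
# region-1 labour clearing replaced by the numeraire condition) plus the
# full quantity system for reporting.
#' @noRd
cge_system <- function(params, z) {
  R <- params$R; S <- params$S
  p <- matrix(exp(z[seq_len(R * S)]), R, S, byrow = TRUE,
              dimnames = dimnames(params$X0))
  w <- exp(z[R * S + seq_len(R)])
  rk <- exp(z[R * S + R + seq_len(R)])

  piL <- w / params$psi          # effective labour price, by (r, s)
  piK <- rk / params$chi
  pva <- matrix(0, R, S)
  for (s in seq_len(S)) {
    sg <- params$sigma_va[s]
    if (abs(sg - 1) < 1e-12) {
      pva[, s] <- piK[, s]^params$thK[, s] * piL[, s]^params$thL[, s]
    } else {
      pva[, s] <- (params$thK[, s] * piK[, s]^(1 - sg) +
                     params$thL[, s] * piL[, s]^(1 - sg))^(1 / (1 - sg))
    }
  }

  # import composite and Armington prices
  PM <- matrix(1, R, S)
  xsrc <- vector("list", R)
  for (d in seq_len(R)) {
    xsrc[[d]] <- vector("list", S)
    for (g in seq_len(S)) {
      cr <- params$cresh[[d]][[g]]
      if (is.null(cr)) next
      al <- cresh_alloc(cr, p[cr$src, g])
      PM[d, g] <- al$pm
      xsrc[[d]][[g]] <- al$x
    }
  }
  sa <- params$sigma_arm
  PA <- matrix(0, R, S)
  for (d in seq_len(R)) for (g in seq_len(S)) {
    if (params$thM[d, g] <= 1e-12) {
      PA[d, g] <- p[d, g]
    } else if (abs(sa - 1) < 1e-12) {
      PA[d, g] <- p[d, g]^params$thD[d, g] * PM[d, g]^params$thM[d, g]
    } else {
      PA[d, g] <- (params$thD[d, g] * p[d, g]^(1 - sa) +
                     params$thM[d, g] * PM[d, g]^(1 - sa))^(1 / (1 - sa))
    }
  }

  # zero profit: price = unit cost
  cost <- matrix(0, R, S)
  for (r in seq_len(R)) for (s in seq_len(S))
    cost[r, s] <- sum(params$A[, s, r] * PA[r, ]) +
      params$va_coef[r, s] * pva[r, s]

  # demands: household income, composite final demand, per-unit sourcing
  Y <- w * params$L_r + rk * params$K_r
  Fq <- params$theta * Y / PA          # composite quantity, final demand
  d_unit <- m_unit <- matrix(0, R, S)
  for (d in seq_len(R)) for (g in seq_len(S)) {
    if (params$thM[d, g] <= 1e-12) {
      d_unit[d, g] <- 1
    } else if (abs(sa - 1) < 1e-12) {
      d_unit[d, g] <- params$thD[d, g] * PA[d, g] / p[d, g]
      m_unit[d, g] <- params$thM[d, g] * PA[d, g] / PM[d, g]
    } else {
      d_unit[d, g] <- params$thD[d, g] * (PA[d, g] / p[d, g])^sa
      m_unit[d, g] <- params$thM[d, g] * (PA[d, g] / PM[d, g])^sa
    }
  }

  # goods market clearing as a linear system in gross outputs X:
  # X_(src,g) = sum_d W[d,src,g] (F_dg + sum_s A[g,s,d] X_ds)
  n <- R * S
  idx <- function(r, s) (r - 1L) * S + s
  W <- array(0, dim = c(R, R, S))   # dest, src, good
  for (d in seq_len(R)) {
    for (g in seq_len(S)) {
      W[d, d, g] <- d_unit[d, g]
      cr <- params$cresh[[d]][[g]]
      if (!is.null(cr))
        W[d, cr$src, g] <- xsrc[[d]][[g]] * m_unit[d, g]
    }
  }
  Mlin <- matrix(0, n, n)
  b <- numeric(n)
  for (src in seq_len(R)) for (g in seq_len(S)) {
    i <- idx(src, g)
    for (d in seq_len(R)) {
      if (W[d, src, g] == 0) next
      b[i] <- b[i] + W[d, src, g] * Fq[d, g]
      for (s2 in seq_len(S))
        Mlin[i, idx(d, s2)] <- Mlin[i, idx(d, s2)] +
          W[d, src, g] * params$A[g, s2, d]
    }
  }
  X <- matrix(solve(diag(n) - Mlin, b), R, S, byrow = TRUE,
              dimnames = dimnames(params$X0))

  # factor demands from Shephard's lemma on the calibrated-share VA cost
  VAq <- params$va_coef * X
  Ld <- Kd <- matrix(0, R, S)
  for (s in seq_len(S)) {
    sg <- params$sigma_va[s]
    ratL <- if (abs(sg - 1) < 1e-12) pva[, s] / piL[, s]
            else (pva[, s] / piL[, s])^sg
    ratK <- if (abs(sg - 1) < 1e-12) pva[, s] / piK[, s]
            else (pva[, s] / piK[, s])^sg
    Ld[, s] <- VAq[, s] * params$thL[, s] * ratL / params$psi[, s]
    Kd[, s] <- VAq[, s] * params$thK[, s] * ratK / params$chi[, s]
  }

  res_zp <- as.vector(t(log(p) - log(cost)))
  res_L <- (rowSums(Ld) - params$L_r) / params$L_r
  res_K <- (rowSums(Kd) - params$K_r) / params$K_r
  walras <- w[1L] * (rowSums(Ld)[1L] - params$L_r[1L])
  numeraire <- (w[1L] * params$L_r[1L] + rk[1L] * params$K_r[1L]) /
    (params$L_r[1L] + params$K_r[1L]) - 1
  res <- c(res_zp, numeraire, res_L[-1L], res_K)

  list(res = res, walras = walras, p = p, w = w, rk = rk, PA = PA, PM = PM,
       pva = pva, X = X, VAq = VAq, Ld = Ld, Kd = Kd, Fq = Fq, Y = Y)
}

#' Solve the general-equilibrium model
#'
#' Damped Newton iteration on log prices starting from the benchmark (all
#' prices one), with a numerical Jacobian. The average factor price of the
#' first region is the numeraire. Market-clearing and zero-profit residuals
#' are driven below `tol`; the value of the Walras-redundant equation is
#' reported as a diagnostic.
#'
#' @param params a `cge_params` (possibly shocked).
#' @param tol residual tolerance (default 1e-8).
#' @param max_iter maximum Newton iterations.
#' @return an object of class `cge_solution`: prices (`p`, `w`, `rk`,
#'   `PA`, `PM`, `pva`), quantities (`X`, `VAq`, `L`, `K`, `F`), household
#'   income `Y`, per-region real GDP (value added at benchmark prices)
#'   in `gdp`, and `diagnostics` (residual norm, iterations, Walras value).
#' @export
solveCGE <- function(params, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(params, "cge_params"))
  n <- params$R * params$S + 2L * params$R
  z <- numeric(n)
  sys <- cge_system(params, z)
  it <- 0L
  while (max(abs(sys$res)) > tol && it < max_iter) {
    it <- it + 1L
    J <- matrix(0, n, n)
    h <- 1e-7
    for (j in seq_len(n)) {
      zj <- z; zj[j] <- zj[j] + h
      J[, j] <- (cge_system(params, zj)$res - sys$res) / h
    }
    step <- tryCatch(solve(J, -sys$res), error = function(e)
      stop("solver error: singular Jacobian at iteration ", it,
           "; residual norm ", signif(max(abs(sys$res)), 3), call. = FALSE))
    lam <- 1
    repeat {
      cand <- tryCatch(cge_system(params, z + lam * step),
                       error = function(e) NULL)
      if (!is.null(cand) && all(is.finite(cand$res)) &&
          max(abs(cand$res)) < max(abs(sys$res))) break
      lam <- lam / 2
      if (lam < 1e-6)
        stop("solver error: line search failed at iteration ", it,
             "; residual norm ", signif(max(abs(sys$res)), 3),
             call. = FALSE)
    }
    z <- z + lam * step
    sys <- cand
  }
  if (max(abs(sys$res)) > tol)
    stop("solver error: no convergence after ", max_iter,
         " iterations; residual norm ", signif(max(abs(sys$res)), 3),
         call. = FALSE)
  gdp <- data.frame(region = params$regions$region,
                    gdp_real = rowSums(sys$VAq),
                    gdp_benchmark = rowSums(params$VA0))
  structure(list(p = sys$p, w = sys$w, rk = sys$rk, PA = sys$PA,
                 PM = sys$PM, pva = sys$pva, X = sys$X, VAq = sys$VAq,
                 L = sys$Ld, K = sys$Kd, F = sys$Fq, Y = sys$Y, gdp = gdp,
                 params = params,
                 diagnostics = list(residual = max(abs(sys$res)),
                                    iterations = it, walras = sys$walras)),
            class = "cge_solution")
}

#' @export
print.cge_solution <- function(x, ...) {
  cat("<cge_solution> ", x$params$R, " regions x ", x$params$S,
      " sectors; residual ", signif(x$diagnostics$residual, 2),
      " after ", x$diagnostics$iterations, " iterations\n", sep = "")
  print(x$gdp)
  invisible(x)
}

#' GDP and GVA impact report
#'
#' Compares a solved equilibrium against a benchmark solution of the same
#' economy: regional real GDP percentage changes, sectoral real GVA
#' percentage changes, and each sector's contribution in percentage points
#' to its region's GVA change (contributions sum exactly to the regional
#' total).
#'
#' @param solution,benchmark `cge_solution` objects over the same economy.
#' @return a list with data frames `regional` (`region`, `gdp_pct`) and
#'   `sectoral` (`region`, `sector`, `gva_pct`, `contribution_pp`).
#' @export
impactReport <- function(solution, benchmark) {
  stopifnot(inherits(solution, "cge_solution"),
            inherits(benchmark, "cge_solution"))
  if (!identical(dim(solution$VAq), dim(benchmark$VAq)))
    stop("invalid input: solutions have different economy dimensions",
         call. = FALSE)
  VA1 <- solution$VAq; VA0 <- benchmark$VAq
  reg_tot0 <- rowSums(VA0)
  regional <- data.frame(region = solution$params$regions$region,
                         gdp_pct = unname(100 * (rowSums(VA1) - reg_tot0) /
                                            reg_tot0))
  rownames(regional) <- NULL
  sectoral <- do.call(rbind, lapply(rownames(VA1), function(r)
    data.frame(region = r, sector = colnames(VA1),
               gva_pct = unname(100 * (VA1[r, ] - VA0[r, ]) / VA0[r, ]),
               contribution_pp = unname(100 * (VA1[r, ] - VA0[r, ]) /
                                          reg_tot0[r]))))
  rownames(sectoral) <- NULL
  list(regional = regional, sectoral = sectoral)
}
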