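# Independent brute-force oracles used to validate the vectorised feature
# engine: explicit pair/run/zone/neighbourhood enumeration with scalar
# loops, and naive direct-formula statistics. These deliberately share no
# code with the package internals.

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# all 26 neighbour offsets
ALL_OFFS <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})
# 13 canonical directions (positive lexicographic half)
HALF_OFFS <- ALL_OFFS[ALL_OFFS[, 3] * 9 + ALL_OFFS[, 2] * 3 + ALL_OFFS[, 1] > 0, ]

inGrid <- function(v, d) all(v >= 1) && all(v <= d)

# --- naive statistics --------------------------------------------------------

ccc_naive <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

dr_naive <- function(x, y) {
  1 - (sum(abs(x - y)) / length(x)) / (max(c(x, y)) - min(c(x, y)))
}

rsq_naive <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  (num / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
}

# --- GLCM oracle -------------------------------------------------------------

# symmetric normalised co-occurrence matrix for one direction, or NULL
oracleGlcmMatrix <- function(lev, Ng, off) {
  d <- dim(lev)
  M <- matrix(0, Ng, Ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k])) next
    v2 <- c(i, j, k) + off
    if (!inGrid(v2, d)) next
    l2 <- lev[v2[1], v2[2], v2[3]]
    if (is.na(l2)) next
    M[lev[i, j, k], l2] <- M[lev[i, j, k], l2] + 1
    M[l2, lev[i, j, k]] <- M[l2, lev[i, j, k]] + 1
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

oracleGlcmFeatures <- function(P) {
  Ng <- nrow(P)
  px <- numeric(Ng)
  for (i in 1:Ng) px[i] <- sum(P[i, ])
  mu_x <- 0; for (i in 1:Ng) mu_x <- mu_x + i * px[i]
  var_x <- 0; for (i in 1:Ng) var_x <- var_x + (i - mu_x)^2 * px[i]
  mu <- 0
  for (i in 1:Ng) for (j in 1:Ng) mu <- mu + i * P[i, j]
  pd <- numeric(Ng); ps <- numeric(2 * Ng - 1)
  for (i in 1:Ng) for (j in 1:Ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  d_avg <- 0; for (k in 0:(Ng - 1)) d_avg <- d_avg + k * pd[k + 1]
  s_avg <- 0; for (k in 2:(2 * Ng)) s_avg <- s_avg + k * ps[k - 1]
  lg <- function(v) if (v > 0) log2(v) else 0
  acc <- c(jvar = 0, jent = 0, dvar = 0, dent = 0, svar = 0, sent = 0,
           asm = 0, contrast = 0, dissim = 0, id = 0, idm = 0, idmn = 0,
           invvar = 0, autoc = 0, ct = 0, cs = 0, cp = 0)
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    acc["jvar"] <- acc["jvar"] + (i - mu)^2 * p
    acc["jent"] <- acc["jent"] - p * lg(p)
    acc["asm"] <- acc["asm"] + p^2
    acc["contrast"] <- acc["contrast"] + (i - j)^2 * p
    acc["dissim"] <- acc["dissim"] + abs(i - j) * p
    acc["id"] <- acc["id"] + p / (1 + abs(i - j))
    acc["idm"] <- acc["idm"] + p / (1 + (i - j)^2)
    acc["idmn"] <- acc["idmn"] + p / (1 + (i - j)^2 / Ng^2)
    if (i != j) acc["invvar"] <- acc["invvar"] + p / (i - j)^2
    acc["autoc"] <- acc["autoc"] + i * j * p
    acc["ct"] <- acc["ct"] + (i + j - 2 * mu_x)^2 * p
    acc["cs"] <- acc["cs"] + (i + j - 2 * mu_x)^3 * p
    acc["cp"] <- acc["cp"] + (i + j - 2 * mu_x)^4 * p
  }
  for (k in 0:(Ng - 1)) {
    acc["dvar"] <- acc["dvar"] + (k - d_avg)^2 * pd[k + 1]
    acc["dent"] <- acc["dent"] - pd[k + 1] * lg(pd[k + 1])
  }
  for (k in 2:(2 * Ng)) {
    acc["svar"] <- acc["svar"] + (k - s_avg)^2 * ps[k - 1]
    acc["sent"] <- acc["sent"] - ps[k - 1] * lg(ps[k - 1])
  }
  HXY <- acc[["jent"]]
  HXY1 <- 0; HXY2 <- 0; HX <- 0
  for (i in 1:Ng) HX <- HX - px[i] * lg(px[i])
  for (i in 1:Ng) for (j in 1:Ng) {
    HXY1 <- HXY1 - P[i, j] * lg(px[i] * px[j])
    HXY2 <- HXY2 - px[i] * px[j] * lg(px[i] * px[j])
  }
  ic1 <- if (HX > 0) (HXY - HXY1) / HX else NaN
  ic2 <- sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0))
  corr <- if (var_x > 0) (acc[["autoc"]] - mu_x^2) / var_x else NaN
  c(`avgCooc_3D_Joint-var` = acc[["jvar"]],
    `avgCooc_3D_Joint-avg` = mu,
    `avgCooc_3D_Joint-entropy` = acc[["jent"]],
    `avgCooc_3D_Difference-var` = acc[["dvar"]],
    `avgCooc_3D_Difference-entropy` = acc[["dent"]],
    `avgCooc_3D_Difference-avg` = d_avg,
    `avgCooc_3D_Sum-var` = acc[["svar"]],
    `avgCooc_3D_Sum-entropy` = acc[["sent"]],
    `avgCooc_3D_Sum-avg` = s_avg,
    `avgCooc_3D_Angular-second-moment` = acc[["asm"]],
    `avgCooc_3D_Contrast` = acc[["contrast"]],
    `avgCooc_3D_Dissimilarity` = acc[["dissim"]],
    `avgCooc_3D_Inv-diff` = acc[["id"]],
    `avgCooc_3D_Inv-diff-mom` = acc[["idm"]],
    `avgCooc_3D_Inv-diff-mom-norm` = acc[["idmn"]],
    `avgCooc_3D_Inverse-variance` = acc[["invvar"]],
    `avgCooc_3D_Correlation` = corr,
    `avgCooc_3D_Autocorrelation` = acc[["autoc"]],
    `avgCooc_3D_Cluster-tendency` = acc[["ct"]],
    `avgCooc_3D_Cluster-shade` = acc[["cs"]],
    `avgCooc_3D_Cluster-prominence` = acc[["cp"]],
    `avgCooc_3D_First-measure-of-information-correlation` = ic1,
    `avgCooc_3D_Second-measure-of-information-correlation` = ic2)
}

oracleGlcm <- function(lev, Ng) {
  mats <- list()
  for (r in seq_len(nrow(HALF_OFFS))) {
    P <- oracleGlcmMatrix(lev, Ng, HALF_OFFS[r, ])
    if (!is.null(P)) mats[[length(mats) + 1]] <- oracleGlcmFeatures(P)
  }
  colMeans(do.call(rbind, mats))
}

# --- GLRLM / GLSZM shared feature formulas (loop form) -----------------------

oracleRlmFeatures <- function(R, Nv) {
  Nr <- sum(R)
  Ng <- nrow(R); Lm <- ncol(R)
  ri <- numeric(Ng); rj <- numeric(Lm)
  for (i in 1:Ng) ri[i] <- sum(R[i, ])
  for (j in 1:Lm) rj[j] <- sum(R[, j])
  mu_i <- 0; mu_j <- 0
  for (i in 1:Ng) mu_i <- mu_i + i * ri[i] / Nr
  for (j in 1:Lm) mu_j <- mu_j + j * rj[j] / Nr
  f <- numeric(16)
  for (i in 1:Ng) for (j in 1:Lm) {
    r <- R[i, j]
    if (r == 0) next
    f[1] <- f[1] + r / j^2
    f[2] <- f[2] + r * j^2
    f[3] <- f[3] + r / i^2
    f[4] <- f[4] + r * i^2
    f[5] <- f[5] + r / (i^2 * j^2)
    f[6] <- f[6] + r * i^2 / j^2
    f[7] <- f[7] + r * j^2 / i^2
    f[8] <- f[8] + r * i^2 * j^2
    f[14] <- f[14] + (i - mu_i)^2 * r / Nr
    f[15] <- f[15] + (j - mu_j)^2 * r / Nr
    f[16] <- f[16] - (r / Nr) * log2(r / Nr)
  }
  f[1:8] <- f[1:8] / Nr
  f[9] <- sum(ri^2) / Nr
  f[10] <- sum(ri^2) / Nr^2
  f[11] <- sum(rj^2) / Nr
  f[12] <- sum(rj^2) / Nr^2
  f[13] <- Nr / Nv
  f
}

# runs by explicit forward walking from run-starts
oracleRlmMatrix <- function(lev, Ng, off) {
  d <- dim(lev)
  R <- matrix(0, Ng, max(d))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- c(i, j, k)
    l0 <- lev[i, j, k]
    if (is.na(l0)) next
    prev <- v - off
    if (inGrid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
        lev[prev[1], prev[2], prev[3]] == l0) next  # not a run start
    len <- 1
    nxt <- v + off
    while (inGrid(nxt, d) && !is.na(lev[nxt[1], nxt[2], nxt[3]]) &&
           lev[nxt[1], nxt[2], nxt[3]] == l0) {
      len <- len + 1
      nxt <- nxt + off
    }
    R[l0, len] <- R[l0, len] + 1
  }
  R
}

oracleGlrlm <- function(lev, Ng) {
  Nv <- sum(!is.na(lev))
  rows <- lapply(seq_len(nrow(HALF_OFFS)), function(r)
    oracleRlmFeatures(oracleRlmMatrix(lev, Ng, HALF_OFFS[r, ]), Nv))
  colMeans(do.call(rbind, rows))
}

# --- GLSZM oracle (BFS flood fill) -------------------------------------------

oracleGlszm <- function(lev, Ng) {
  d <- dim(lev)
  visited <- array(FALSE, dim = d)
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k]) || visited[i, j, k]) next
    l0 <- lev[i, j, k]
    queue <- list(c(i, j, k))
    visited[i, j, k] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(ALL_OFFS))) {
        u <- v + ALL_OFFS[r, ]
        if (!inGrid(u, d)) next
        if (visited[u[1], u[2], u[3]]) next
        lu <- lev[u[1], u[2], u[3]]
        if (is.na(lu) || lu != l0) next
        visited[u[1], u[2], u[3]] <- TRUE
        queue[[length(queue) + 1]] <- u
      }
    }
    zones[[length(zones) + 1]] <- c(l0, size)
  }
  zm <- do.call(rbind, zones)
  S <- matrix(0, Ng, max(zm[, 2]))
  for (z in seq_len(nrow(zm))) S[zm[z, 1], zm[z, 2]] <- S[zm[z, 1], zm[z, 2]] + 1
  oracleRlmFeatures(S, sum(!is.na(lev)))
}

# --- NGTDM oracle ------------------------------------------------------------

oracleNgtdm <- function(lev, Ng) {
  d <- dim(lev)
  s <- numeric(Ng); ni <- numeric(Ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    l0 <- lev[i, j, k]
    if (is.na(l0)) next
    nb <- c()
    for (r in seq_len(nrow(ALL_OFFS))) {
      u <- c(i, j, k) + ALL_OFFS[r, ]
      if (!inGrid(u, d)) next
      lu <- lev[u[1], u[2], u[3]]
      if (!is.na(lu)) nb <- c(nb, lu)
    }
    if (!length(nb)) next
    ni[l0] <- ni[l0] + 1
    s[l0] <- s[l0] + abs(l0 - sum(nb) / length(nb))
  }
  Nvc <- sum(ni)
  p <- ni / Nvc
  present <- which(p > 0)
  Ngp <- length(present)
  eps <- 1e-12
  coarse <- if (sum(p * s) > eps) 1 / sum(p * s) else 1 / eps
  contrast <- 0; busy_den <- 0; cmplx <- 0; strength <- 0
  if (Ngp > 1) {
    for (a in present) for (b in present) {
      contrast <- contrast + p[a] * p[b] * (a - b)^2
      if (a != b) {
        cmplx <- cmplx + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
        strength <- strength + (p[a] + p[b]) * (a - b)^2
      }
    }
    contrast <- contrast / (Ngp * (Ngp - 1)) * sum(s) / Nvc
    cmplx <- cmplx / Nvc
  }
  for (a in present) for (b in present)
    busy_den <- busy_den + abs(a * p[a] - b * p[b])
  busy <- if (busy_den > 0) sum(p * s) / busy_den else 0
  strength <- strength / (eps + sum(s))
  c(NGTDM_Coarseness = coarse, NGTDM_Contrast = contrast,
    NGTDM_Busyness = busy, NGTDM_Complexity = cmplx,
    NGTDM_Strength = strength)
}

# --- direct (non-separable) 3D correlation oracle ----------------------------

# symmetric (edge-inclusive) padding index
padIdx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracleConv3 <- function(a, kx, ky, kz) {
  d <- dim(a)
  cx <- (length(kx) - 1) %/% 2
  cy <- (length(ky) - 1) %/% 2
  cz <- (length(kz) - 1) %/% 2
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a1 in seq_along(kx)) for (a2 in seq_along(ky)) for (a3 in seq_along(kz)) {
      acc <- acc + kx[a1] * ky[a2] * kz[a3] *
        a[padIdx(i + a1 - 1 - cx, d[1]),
          padIdx(j + a2 - 1 - cy, d[2]),
          padIdx(k + a3 - 1 - cz, d[3])]
    }
    out[i, j, k] <- acc
  }
  out
}

# --- fixture builders --------------------------------------------------------

# random quantised 4x4x4 ROI (partial random mask, Ng levels)
randomQuantizedROI <- function(Ng = 4, p_mask = 0.7, dims = c(4, 4, 4)) {
  vol <- ScanVolume(array(stats::rnorm(prod(dims)), dim = dims))
  repeat {
    m <- array(stats::runif(prod(dims)) < p_mask, dim = dims)
    if (sum(m) >= 8) break
  }
  quantizeROI(vol, RegionMask(m), Ng = Ng)
}

# small ScanVolume + cuboid ROI pair on an isotropic grid
cuboidFixture <- function(dims = c(12, 12, 12), lo = 4, hi = 9,
                          spacing = c(1, 1, 1), f = function(n) stats::rnorm(n)) {
  v <- ScanVolume(array(f(prod(dims)), dim = dims), spacing = spacing)
  m <- array(0L, dim = dims)
  m[lo:hi, lo:hi, lo:hi] <- 1L
  list(vol = v, roi = RegionMask(m, spacing = spacing))
}
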