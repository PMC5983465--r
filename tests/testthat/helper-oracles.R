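# Shared fixtures and independent oracles used across test files.

# A mid-range life history satisfying all joint constraints.
midLife <- function(h = 0.6, A_max = 30, age_mat = 8, Linf = 120,
                    Lmat = 60) {
  list(A_max = A_max, age_mat = age_mat, Linf = Linf, Lmat = Lmat, h = h,
       M = -log(0.01) / A_max, K = -log(1 - Lmat / Linf) / age_mat,
       t0 = 0, lw_a = 1e-5, lw_b = 3, r = NA_real_)
}

midFleet <- function(availability = 0.8, dome_sel = 0.9, Lc = 55,
                     discard_rate = 0.1, discard_mortality = 0.9) {
  list(availability = availability, dome_sel = dome_sel, Lc = Lc,
       discard_rate = discard_rate, discard_mortality = discard_mortality)
}

midOM <- function(life = midLife(), fleet = midFleet(), depletion = 0.3,
                  sigmaR = 0.5, rho = 0.3, seed = 1L,
                  variant = "sPSA") {
  scores <- setNames(rep(2L, nrow(psaAttributes(variant))),
                     psaAttributes(variant)$name)
  new("OperatingModel", variant = variant, scores = scores, life = life,
      fleet = fleet, depletion = depletion, sigmaR = sigmaR, rho = rho,
      seed = as.integer(seed))
}

# Independent demographic oracle: log of the dominant eigenvalue of the
# Leslie matrix over ages 1..A_max with fecundities alpha0 * mat_a * w_a
# discounted by one year of parental survival, schedules recomputed here
# from first principles.
leslieLogLambda <- function(life) {
  A <- ceiling(life$A_max)
  a <- 1:A
  L <- life$Linf * (1 - exp(-life$K * a))
  w <- L^3
  mat <- 1 / (1 + exp(-log(19) * (L - life$Lmat) / (0.1 * life$Lmat)))
  l <- exp(-life$M * a)
  spr0 <- sum(l * mat * w)
  alpha0 <- 4 * life$h / ((1 - life$h) * spr0)
  m <- alpha0 * mat * w
  Lm <- matrix(0, A, A)
  Lm[1, ] <- m * exp(-life$M)
  for (i in seq_len(A - 1)) Lm[i + 1, i] <- exp(-life$M)
  log(Re(eigen(Lm, only.values = TRUE)$values[1]))
}

# Exact terciles of V = sqrt(P^2 + S^2) for P, S iid U(1, 3), by 2-D
# numeric integration of the uniform density over the disc P^2 + S^2 <= c^2.
tercileOracle <- function(prob) {
  cdf <- function(c) {
    f <- function(p) pmin(3, pmax(1, sqrt(pmax(0, c^2 - p^2)))) - 1
    stats::integrate(f, 1, 3, rel.tol = 1e-10)$value / 4
  }
  vapply(prob, function(q)
    stats::uniroot(function(c) cdf(c) - q, c(sqrt(2), sqrt(18)),
                   tol = 1e-9)$root, numeric(1))
}
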