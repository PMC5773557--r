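# Latent log2FC trajectory shapes, interpolated onto the configured grid.
# The late-rising shape peaks at 9 h and stays elevated through 24 h (value 1
# at the endpoint so it scales directly by the planted endpoint log2FC); the
# TF shape is induced by 1 h, peaks at 4-6 h and remains positive; the
# suppressed shape declines monotonically to -1 at 24 h.
shape_late_rising <- function(hours) {
  stats::approx(x = c(0, 1, 2, 3, 4, 6, 9, 12, 16, 20, 24),
                y = c(0, 0.05, 0.12, 0.22, 0.35, 0.65, 1.10, 1.05, 1.02, 1.00,
                      1.00),
                xout = hours, rule = 2)$y
}

shape_early_tf <- function(hours) {
  stats::approx(x = c(0, 1, 2, 3, 4, 5, 6, 9, 12, 16, 20, 24),
                y = c(0, 0.55, 0.75, 0.90, 1.00, 1.00, 1.00, 0.80, 0.65, 0.55,
                      0.50, 0.45),
                xout = hours, rule = 2)$y
}

shape_suppressed <- function(hours) {
  stats::approx(x = c(0, 1, 3, 6, 9, 12, 16, 20, 24),
                y = -c(0, 0.10, 0.30, 0.55, 0.70, 0.80, 0.90, 0.95, 1.00),
                xout = hours, rule = 2)$y
}

# Draw the two planted latent log2FC profiles so that the *sample* Pearson
# correlation of the pair lands on rho, not merely its expectation: the two
# noise vectors are drawn Gaussian and then projected orthogonal (in the
# sample sense) to the intercept, to the shared trajectory and to the
# endpoint coordinate, orthogonalized against each other, and scaled to an
# exact sample variance. With signal variance S across the grid and noise
# variance v per gene, the latent sample correlation is exactly S/(S + v);
# v is chosen as S(1-rho)/rho minus the expected counting-noise variance of
# log2 NB counts (delta method), so the correlation observed after counting
# noise is centered on rho with only the small counting jitter around it.
# Orthogonality to the endpoint coordinate makes the latent endpoint log2FC
# exactly the planted value.
planted_latents <- function(shared_fc, rho, mu0, phi) {
  n <- length(shared_fc)
  S <- stats::var(shared_fc)
  if (S <= 0 || rho >= 1) {
    return(list(shared_fc, shared_fc))
  }
  v_count <- mean(((1 / mu0 + phi) +
                   (1 / (mu0 * 2^shared_fc) + phi)) / log(2)^2)
  sigma2 <- max(0, S * (1 - rho) / rho - v_count)
  if (sigma2 == 0) return(list(shared_fc, shared_fc))
  basis <- cbind(1, shared_fc, c(rep(0, n - 1), 1))
  Q <- qr.Q(qr(basis))
  z <- matrix(rnorm(2L * n), n, 2L)
  z <- z - Q %*% (t(Q) %*% z)
  z2 <- z[, 2] - z[, 1] * sum(z[, 1] * z[, 2]) / sum(z[, 1]^2)
  scale_to <- function(u) u * sqrt(sigma2 * (n - 1) / sum(u^2))
  list(shared_fc + scale_to(z[, 1]), shared_fc + scale_to(z2))
}

#' Simulate a two-condition time-course count matrix
#'
#' Draws negative-binomial counts per gene, condition (PS treatment, OS
#' control) and timepoint. The planted elncRNA and its target gene share a
#' latent late-rising log2 fold-change trajectory, scaled so the expected
#' endpoint log2FC equals `planted_endpoint_log2fc` and perturbed with
#' calibrated gene-specific noise so the expected Pearson correlation of
#' their observed log2FC profiles equals `planted_correlation`. TF-like genes
#' peak at 4-6 h, the suppressed gene falls to a negative endpoint log2FC,
#' and neighbor/background genes have exchangeable flat trajectories.
#'
#' @param annotation A `world_annotation` from [generate_annotation()].
#' @param config The [world_config()] used to build it.
#' @return A [timecourse_matrix()] whose genes follow the annotation order.
#' @export
simulate_timecourse <- function(annotation, config) {
  validate_world_config(config)
  genes <- annotation$genes
  hours <- config$timepoints_h
  n_t <- length(hours)
  fc <- config$planted_endpoint_log2fc
  shared <- fc * shape_late_rising(hours)

  mu0_planted <- 20000
  phi_planted <- 0.001

  with_seed(substream(config$seed, 4L), {
    pl <- planted_latents(shared, config$planted_correlation,
                          mu0_planted, phi_planted)
    latent <- matrix(0, nrow = nrow(genes), ncol = n_t)
    baseline <- numeric(nrow(genes))
    phi <- rep(config$nb_dispersion, nrow(genes))
    for (i in seq_len(nrow(genes))) {
      role <- genes$role[i]
      if (role %in% c("elncRNA", "target")) {
        latent[i, ] <- if (role == "elncRNA") pl[[1]] else pl[[2]]
        baseline[i] <- mu0_planted
        phi[i] <- phi_planted
      } else if (role == "tf") {
        latent[i, ] <- 1.5 * shape_early_tf(hours)
        baseline[i] <- 2000
      } else if (role == "suppressed") {
        latent[i, ] <- 1.5 * shape_suppressed(hours)
        baseline[i] <- 2000
      } else if (role == "neighbor") {
        baseline[i] <- 500
      } else {
        baseline[i] <- max(5, stats::rlnorm(1, log(100), 1))
      }
    }
    vals <- array(0, dim = c(nrow(genes), 2, n_t),
                  dimnames = list(genes$gene_id, c("PS", "OS"), hours))
    for (t in seq_len(n_t)) {
      mu_ps <- baseline * 2^latent[, t]
      vals[, 1, t] <- rnbinom(nrow(genes), mu = mu_ps, size = 1 / phi)
      vals[, 2, t] <- rnbinom(nrow(genes), mu = baseline, size = 1 / phi)
    }
    timecourse_matrix(vals, genes$biotype, hours)
  })
}
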