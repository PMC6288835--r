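# Synthetic F2 intercross generator and the SLM-vs-DGLM power engine.

#' Simulation configuration for an F2 intercross
#'
#' Describes the mapping population and generative model used by
#' [simulate_f2()]. Genotypes follow the F2 Markov chain along each
#' chromosome (first marker drawn from (1/4, 1/2, 1/4); transitions from
#' the Haldane recombination fraction for the marker spacing), sex is
#' Bernoulli(1/2), and the phenotype is drawn from the mean-variance model
#' \deqn{y_i \sim N(m_i, e^{2 v_i}), \quad
#'   m_i = \mu + sex_i \beta_{sex} + a_i \beta_a + d_i \beta_d, \quad
#'   v_i = \mu_v + sex_i \gamma_{sex} + a_i \gamma_a + d_i \gamma_d,}
#' with \eqn{a_i, d_i} the (known) additive/dominance coding at the QTL.
#' Defaults mirror a typical mouse intercross: 244 individuals (the size
#' of the circadian case-study cross) and 3 chromosomes of 11 markers at
#' 10 cM spacing; all effects default to 0 (a global-null cross).
#'
#' @param n Number of F2 individuals (>= 2).
#' @param chromosomes Number of chromosomes (named "1", "2", ...).
#' @param markers_per_chr Markers per chromosome.
#' @param spacing Marker spacing in cM (> 0).
#' @param qtl `NULL`, or a list with `chr`, `pos` (cM), and effects
#'   `beta_a`, `beta_d` (mean) and `gamma_a`, `gamma_d` (log residual SD);
#'   the QTL is placed at the nearest marker.
#' @param mu,mu_v Baseline mean and log residual SD.
#' @param beta_sex,gamma_sex Sex effects on the mean and log residual SD.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @examples
#' sim_config(n = 100, qtl = list(chr = "1", pos = 50, beta_a = 1))
#' @export
sim_config <- function(n = 244, chromosomes = 3, markers_per_chr = 11,
                       spacing = 10, qtl = NULL, mu = 0, mu_v = 0,
                       beta_sex = 0, gamma_sex = 0, seed = 1) {
  if (n < 2) bail("`n` must be >= 2.")
  if (spacing <= 0) bail("`spacing` must be > 0.")
  if (markers_per_chr < 1) bail("`markers_per_chr` must be >= 1.")
  chr_names <- as.character(seq_len(chromosomes))
  if (!is.null(qtl)) {
    qtl <- utils::modifyList(
      list(chr = chr_names[1], pos = 0, beta_a = 0, beta_d = 0,
           gamma_a = 0, gamma_d = 0), qtl)
    qtl$chr <- as.character(qtl$chr)
    if (!qtl$chr %in% chr_names) {
      bail("QTL chromosome '", qtl$chr, "' is not in the simulated map.")
    }
  }
  structure(list(n = as.integer(n), chromosomes = as.integer(chromosomes),
                 markers_per_chr = as.integer(markers_per_chr),
                 spacing = spacing, qtl = qtl, mu = mu, mu_v = mu_v,
                 beta_sex = beta_sex, gamma_sex = gamma_sex,
                 seed = assert_seed(seed)),
            class = "sim_config")
}

#' Simulate an F2 intercross
#'
#' Draws genotypes, sex, and a phenotype `y` from the generative model in
#' [sim_config()]. The realized QTL marker and true parameters are stored
#' in `attr(, "truth")`.
#'
#' @param config A [sim_config()].
#' @return An [new_cross()] `f2cross`; `pheno` holds `id`, `y`, `sex`.
#' @examples
#' cr <- simulate_f2(sim_config(n = 50, seed = 7))
#' cr
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  map <- tidyr::expand_grid(chr = as.character(seq_len(cfg$chromosomes)),
                            idx = seq_len(cfg$markers_per_chr)) |>
    dplyr::mutate(pos = (.data$idx - 1) * cfg$spacing,
                  marker = sprintf("m%s_%02d", .data$chr, .data$idx)) |>
    dplyr::select("marker", "chr", "pos")

  r <- haldane(cfg$spacing)
  Tm <- f2_transition(r)
  cumT <- t(apply(Tm, 1, cumsum))

  withr::with_seed(cfg$seed, {
    n <- cfg$n
    G <- matrix(0L, n, nrow(map))
    col <- 0
    for (ch in seq_len(cfg$chromosomes)) {
      g <- sample.int(3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
      col <- col + 1
      G[, col] <- g
      if (cfg$markers_per_chr > 1) {
        for (m in 2:cfg$markers_per_chr) {
          u <- runif(n)
          P <- cumT[g, , drop = FALSE]
          g <- 1L + (u > P[, 1]) + (u > P[, 2])
          col <- col + 1
          G[, col] <- g
        }
      }
    }
    sex <- rbinom(n, 1, 0.5)
    if (!is.null(cfg$qtl)) {
      on_chr <- which(map$chr == cfg$qtl$chr)
      qmarker <- on_chr[which.min(abs(map$pos[on_chr] - cfg$qtl$pos))]
      gq <- G[, qmarker]
      a <- gq - 1
      d <- as.numeric(gq == 2)
      qtl_effects <- cfg$qtl
    } else {
      qmarker <- NA_integer_
      a <- d <- numeric(n)
      qtl_effects <- list(beta_a = 0, beta_d = 0, gamma_a = 0, gamma_d = 0)
    }
    m <- cfg$mu + sex * cfg$beta_sex + a * qtl_effects$beta_a +
      d * qtl_effects$beta_d
    v <- cfg$mu_v + sex * cfg$gamma_sex + a * qtl_effects$gamma_a +
      d * qtl_effects$gamma_d
    y <- rnorm(n, m, exp(v))

    geno <- matrix(c("AA", "AB", "BB")[G], n, nrow(map))
    cross <- new_cross(geno, map,
                       tibble::tibble(id = as.character(seq_len(n)),
                                      y = y, sex = sex))
    attr(cross, "truth") <- list(
      config = unclass(cfg),
      qtl_marker = if (is.na(qmarker)) NULL else map$marker[qmarker])
    cross
  })
}

#' Effect specification for power simulations
#'
#' Coefficients of the single-locus generative model used by
#' [power_compare()] and [sample_size_equivalent()]. Mean effects
#' (`beta_*`) are on the phenotype scale; variance effects (`gamma_*`) are
#' on the log residual SD scale. Typically these are the DGLM coefficients
#' fitted at a detected QTL (see [fit_dglm()]).
#'
#' @param mu,beta_sex,beta_a,beta_d Mean-submodel coefficients.
#' @param mu_v,gamma_sex,gamma_a,gamma_d Log-SD-submodel coefficients.
#' @return A named list of class `qtl_effects`.
#' @export
qtl_effects <- function(mu = 0, beta_sex = 0, beta_a = 0, beta_d = 0,
                        mu_v = 0, gamma_sex = 0, gamma_a = 0, gamma_d = 0) {
  structure(list(mu = mu, beta_sex = beta_sex, beta_a = beta_a,
                 beta_d = beta_d, mu_v = mu_v, gamma_sex = gamma_sex,
                 gamma_a = gamma_a, gamma_d = gamma_d),
            class = "qtl_effects")
}

# one single-locus replicate: exact 1:2:1 genotype draw, Bernoulli sex,
# phenotype from the mean-variance model; returns the two LR statistics
sim_single_locus <- function(effects, n) {
  g <- sample.int(3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  a <- g - 1
  d <- as.numeric(g == 2)
  sex <- rbinom(n, 1, 0.5)
  m <- effects$mu + sex * effects$beta_sex + a * effects$beta_a +
    d * effects$beta_d
  v <- effects$mu_v + sex * effects$gamma_sex + a * effects$gamma_a +
    d * effects$gamma_d
  y <- rnorm(n, m, exp(v))
  list(y = y, sex = sex, a = a, d = d)
}

power_lr_once <- function(effects, n, do_dglm = TRUE) {
  s <- sim_single_locus(effects, n)
  if (sd(s$a) == 0 || sd(s$d) == 0) return(c(NA_real_, NA_real_))
  Xc <- cbind(1, sex = s$sex)
  Xf <- cbind(Xc, a = s$a, d = s$d)
  f0 <- cpp_slm_fit(s$y, Xc)
  f1 <- cpp_slm_fit(s$y, Xf)
  lr_slm <- n * log(f0$rss / f1$rss)
  lr_dglm <- NA_real_
  if (do_dglm) {
    full <- cpp_dglm_fit(s$y, Xf, Xf)
    null_m <- cpp_dglm_fit(s$y, Xc, Xf)
    lr_dglm <- max(0, 2 * (full$loglik - null_m$loglik))
  }
  c(lr_slm, lr_dglm)
}

#' Power comparison of SLM vs. DGLM mQTL tests
#'
#' Monte-Carlo power (or type-I error, when all effects are zero) of the
#' traditional SLM likelihood-ratio test and the DGLM mQTL test at a
#' single locus. Each replicate draws genotype (exact 1:2:1 probabilities),
#' sex, and phenotype from the generative model in [qtl_effects()], and
#' each test rejects when its LR statistic exceeds the upper-`alpha`
#' quantile of the chi-squared distribution with 2 degrees of freedom (a
#' fixed pointwise threshold, as appropriate for a genome-wide significance
#' cutoff like `alpha = 5e-4`).
#'
#' @param effects A [qtl_effects()].
#' @param n Individuals per replicate.
#' @param alpha Pointwise significance level in (0, 1).
#' @param n_sim Number of replicates (>= 100).
#' @param seed Integer seed.
#' @return A `power_result` tibble: one row per method (`slm`,
#'   `dglm_mqtl`) with `power`, `mcse` (= sqrt(p(1-p)/n_sim)), `alpha`,
#'   `n`, `n_sim`, `seed`.
#' @examples
#' power_compare(qtl_effects(beta_a = 0.5, gamma_a = -0.3), n = 200,
#'               alpha = 0.001, n_sim = 200, seed = 1)
#' @export
power_compare <- function(effects, n = 244, alpha = 5e-4, n_sim = 1000,
                          seed = 1) {
  stopifnot(inherits(effects, "qtl_effects"), alpha > 0, alpha < 1)
  if (n_sim < 100) bail("`n_sim` must be >= 100.")
  seed <- assert_seed(seed)
  crit <- qchisq(1 - alpha, df = 2)
  lrs <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), \(i) power_lr_once(effects, n), numeric(2))
  })
  ok <- colSums(is.na(lrs)) == 0
  rej_slm <- mean(lrs[1, ok] > crit)
  rej_dglm <- mean(lrs[2, ok] > crit)
  out <- tibble::tibble(
    method = c("slm", "dglm_mqtl"),
    power = c(rej_slm, rej_dglm),
    mcse = sqrt(c(rej_slm, rej_dglm) * (1 - c(rej_slm, rej_dglm)) / sum(ok)),
    alpha = alpha, n = n, n_sim = sum(ok), seed = seed)
  class(out) <- c("power_result", class(out))
  out
}

#' Sample size giving the SLM the power of the DGLM
#'
#' Searches (on a grid of sample sizes, step `step`) for the smallest `n`
#' at which the SLM test's power matches the DGLM mQTL test's power at the
#' reference sample size, within Monte-Carlo error. This expresses the
#' DGLM's power advantage at a QTL as an equivalent number of additional
#' individuals.
#'
#' @inheritParams power_compare
#' @param n_ref Reference sample size (the actual cross size).
#' @param step Grid step for the search.
#' @param n_max Upper search bound.
#' @return A list: `n_equivalent`, `target_power` (DGLM at `n_ref`),
#'   `slm_power_at_n` and the search trace tibble `trace`.
#' @export
sample_size_equivalent <- function(effects, alpha = 5e-4, n_ref = 244,
                                   n_sim = 1000, seed = 1, step = 10,
                                   n_max = 2000) {
  seed <- assert_seed(seed)
  ref <- power_compare(effects, n = n_ref, alpha = alpha, n_sim = n_sim,
                       seed = seed)
  target <- ref$power[ref$method == "dglm_mqtl"]
  target_mcse <- ref$mcse[ref$method == "dglm_mqtl"]
  crit <- qchisq(1 - alpha, df = 2)
  trace <- list()
  n_grid <- seq(n_ref, n_max, by = step)
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    lrs <- withr::with_seed(seed + i, {
      vapply(seq_len(n_sim), \(j) power_lr_once(effects, n, do_dglm = FALSE)[1],
             numeric(1))
    })
    p <- mean(lrs > crit, na.rm = TRUE)
    mcse <- sqrt(p * (1 - p) / sum(!is.na(lrs)))
    trace[[i]] <- tibble::tibble(n = n, slm_power = p, mcse = mcse)
    if (p >= target - sqrt(mcse^2 + target_mcse^2)) {
      return(list(n_equivalent = n, target_power = target,
                  slm_power_at_n = p,
                  trace = dplyr::bind_rows(trace)))
    }
  }
  bail("SLM power does not reach the DGLM reference power within [",
       n_ref, ", ", n_max, "].")
}

#' @method autoplot power_result
#' @export
autoplot.power_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data$power)) +
    ggplot2::geom_col(width = 0.5, fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$power - 2 * .data$mcse,
                                        ymax = .data$power + 2 * .data$mcse),
                           width = 0.15) +
    ggplot2::labs(y = paste0("rejection rate at alpha = ",
                             format(object$alpha[1])),
                  x = NULL) +
    ggplot2::theme_minimal()
}
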