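# Builders for harmonized instrument tables and random test inputs.

make_harmonized <- function(bx, by, sx = rep(0.005, length(bx)),
                            sy = rep(0.01, length(bx)),
                            rsid = sprintf("rs%d", seq_along(bx)),
                            status = rep("included", length(bx))) {
  structure(
    data.frame(rsid = rsid,
               effect_allele = rep("A", length(bx)),
               other_allele = rep("G", length(bx)),
               beta_exposure = bx, se_exposure = sx,
               eaf_exposure = NA_real_,
               beta_outcome = by, se_outcome = sy,
               eaf_outcome = NA_real_,
               status = status, reason = NA_character_,
               proxy_of = NA_character_,
               stringsAsFactors = FALSE),
    class = c("mr_harmonized", "data.frame"))
}

random_harmonized <- function(J, seed) {
  set.seed(seed)
  make_harmonized(bx = runif(J, 0.01, 0.1) * sample(c(-1, 1), J, TRUE),
                  by = rnorm(J, 0, 0.02),
                  sx = runif(J, 0.001, 0.01),
                  sy = runif(J, 0.005, 0.02))
}

# closed-form weighted least squares through the origin (independent oracle)
ivw_oracle <- function(bx, by, sy) {
  w <- 1 / sy^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - theta * bx)^2)
  list(theta = theta, se_fixed = se_fixed, Q = Q)
}

forward_harmonized <- function() {
  fx <- mr_fixture("vitd_to_adhd")
  harmonize(fx$exposure, fx$outcome)
}

reverse_harmonized <- function() {
  fx <- mr_fixture("adhd_to_vitd")
  harmonize(fx$exposure, fx$outcome)
}
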