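# Shared fixtures: all synthetic, built in code at test time.

fig3_observer <- function(p_jump, sigma_t) {
  categorical_params(p_jump, sigma_jump = 2, sigma_nojump = 0.017,
                     sigma_t = sigma_t)
}

# independent root-finding oracle for the zero-mean criterion: solves the
# log posterior-odds equality in xhat directly from the Gaussian densities
criterion_root_oracle <- function(params) {
  f <- function(xhat) {
    dnorm(xhat, params$mu_jump,
          sqrt(params$sigma_jump^2 + params$sigma_t^2), log = TRUE) +
      log(params$p_jump) -
      dnorm(xhat, params$mu_nojump,
            sqrt(params$sigma_nojump^2 + params$sigma_t^2), log = TRUE) -
      log(1 - params$p_jump)
  }
  uniroot(f, c(1e-8, 50), tol = 1e-12)$root^2
}

# small trial table with binary responses built from explicit counts
table_from_counts <- function(n_jump, n_hit, n_nojump, n_fa) {
  data.frame(
    jumped = rep(c(TRUE, FALSE), c(n_jump, n_nojump)),
    displacement_deg = rep(c(1, 0), c(n_jump, n_nojump)),
    response = c(rep(1:0, c(n_hit, n_jump - n_hit)),
                 rep(1:0, c(n_fa, n_nojump - n_fa)))
  )
}
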