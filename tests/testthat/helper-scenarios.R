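# Simulated SNP-pattern scenarios where the association is either purely
# contamination-driven (genotype -> cell fraction -> pattern) or a direct
# genotype effect with independent contamination.

.contaminationScenario <- function(seed, driven) {
  set.seed(seed)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  frac <- if (driven) pmin(0.08 * g + abs(rnorm(n, sd = 0.05)), 0.5)
          else pmin(abs(rnorm(n, sd = 0.08)), 0.5)
  prof <- runif(30, 3, 6)
  expr <- outer(prof, frac) + matrix(rnorm(30 * n, sd = 0.3), 30, n)
  dimnames(expr) <- list(paste0("ctg", 1:30), paste0("s", 1:n))
  sur <- buildSurrogates(ExpressionData(expr, transformState = "arcsinh"),
                         list(ct1 = rownames(expr)))
  pat <- if (driven) 3 * frac + rnorm(n, sd = 0.2) else 0.7 * g + rnorm(n)
  adjustAssociation(pat, g, sur)
}
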