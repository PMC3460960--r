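# Shared fixtures, built in code at test time.

# A tiny panel: 3 target probes in quadruplicate + 2 empty spots.
tiny_panel <- function() {
  probe_panel(c("p1", "p2", "p3", "e1", "e2"),
              c("miR-a", "miR-b;miR-c", "miR-d", "", ""),
              is_empty = c(FALSE, FALSE, FALSE, TRUE, TRUE),
              is_human = c(TRUE, TRUE, TRUE, FALSE, FALSE))
}

tiny_spot_table <- function(array_id = "A1", panel = tiny_panel()) {
  set.seed(7)
  probes <- rep(c("p1", "p2", "p3"), each = 4)
  spot_table(array_id,
             c(probes, "e1", "e2"),
             c(rep(1:4, 3), 1, 1),
             round(runif(14, 50, 500), 3),
             round(runif(14, 50, 500), 3),
             panel = panel)
}

# Down-scaled synthetic study: same structure as the default conditions,
# smaller probe complement, for fast unit tests.
small_config <- function(...) {
  args <- list(n_probes = 80, n_empty_spots = 60, n_de_probes = 8,
               n_age_probes = 6, seed = 404)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# Latent-level log2 matrix with a planted separating pair and strong DE
# probes; bypasses the spot-level pipeline for classifier/CV tests.
latent_matrix <- function(n_probes = 40, n_case = 10, n_control = 11,
                          lfc = 1.5, n_de = 6, seed = 99, noise = 0.5) {
  set.seed(seed)
  n <- n_case + n_control
  cls <- rep(c("case", "control"), c(n_case, n_control))
  m <- matrix(rnorm(n_probes * n, 7, noise), n_probes, n,
              dimnames = list(sprintf("g%03d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n))))
  if (n_de > 0)
    m[seq_len(n_de), cls == "case"] <-
      m[seq_len(n_de), cls == "case"] + lfc
  # planted pair on the last two probes: shared baseline, reversed margin
  base <- rnorm(n, 9, 0.3)
  sgn <- ifelse(cls == "case", 1, -1)
  m[n_probes - 1, ] <- base + sgn * 2
  m[n_probes, ] <- base - sgn * 2
  list(matrix = m, classes = cls,
       pair = rownames(m)[c(n_probes - 1, n_probes)])
}
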