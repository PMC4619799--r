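# Shared fixtures, memoised so expensive simulations run once per session.
.pk_cache <- new.env(parent = emptyenv())

pk_cached <- function(name, expr) {
  if (!exists(name, envir = .pk_cache, inherits = FALSE))
    assign(name, force(expr), envir = .pk_cache)
  get(name, envir = .pk_cache)
}

hairpin16 <- function() pk_cached("hairpin16", make_ideal("hairpin", 16))

hairpin16_model <- function() pk_cached("hairpin16_model", {
  hp <- hairpin16()
  build_go_model(hp, build_contact_map(hp))
})

hairpin16_pull <- function() pk_cached("hairpin16_pull",
  pull_constant_speed(hairpin16_model(), go_params(seed = 1)))

extended16_model <- function() pk_cached("extended16_model", {
  e <- make_ideal("extended", 16)
  build_go_model(e, build_contact_map(e))
})

trefoil80 <- function() pk_cached("trefoil80",
  make_knotted_chain(80, "3_1", c(19, 25), seed = 4))

trefoil80_core <- function() pk_cached("trefoil80_core",
  knot_core(trefoil80(), seed = 9))

# brute-force all-atom-pair contact oracle (independent of the package scan)
oracle_contacts <- function(cf, min_separation = 3L) {
  tab <- default_radii()
  at <- cf$atoms
  n <- n_residues(cf)
  hits <- NULL
  for (i in seq_len(n - min_separation)) {
    for (j in (i + min_separation):n) {
      ai <- at[at$resid == i, ]
      aj <- at[at$resid == j, ]
      found <- FALSE
      for (a in seq_len(nrow(ai))) {
        for (b in seq_len(nrow(aj))) {
          ra <- atom_radius_single(ai$elety[a], tab)
          rb <- atom_radius_single(aj$elety[b], tab)
          dd <- sqrt((ai$x[a] - aj$x[b])^2 + (ai$y[a] - aj$y[b])^2 +
                       (ai$z[a] - aj$z[b])^2)
          if (dd < ra + rb) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) hits <- rbind(hits, c(i, j))
    }
  }
  hits
}

atom_radius_single <- function(name, tab) {
  r <- tab$radii[name]
  if (is.na(r)) r <- tab$fallback[substr(name, 1, 1)]
  unname(r) * tab$enlargement
}

# a random proper rotation matrix
random_proper_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
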