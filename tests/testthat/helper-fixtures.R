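# Shared simulated fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small panel: quick checks of table plumbing and invariances
panel_small <- function() {
  fixture("panel_small", function() {
    simulate_cross(cross_design(60, seed = 42), sim_genetic_map(120))
  })
}

# power panel: study-sized strain count on a moderate map, for detection
# and recovery tests where n = 357 matters but marker density less so
panel_power <- function() {
  fixture("panel_power", function() {
    simulate_cross(cross_design(357, seed = 42), sim_genetic_map(300))
  })
}

# a map of many short chromosomes: independent segregation makes
# heterozygosity counts approximately binomial across chromosomes
map_indep <- function(n_chrom = 20, markers_per = 5, len_cM = 10) {
  k <- n_chrom * markers_per
  genetic_map(
    marker = sprintf("c%02d_m%d", rep(seq_len(n_chrom), each = markers_per),
                     rep(seq_len(markers_per), n_chrom)),
    chrom = sprintf("c%02d", rep(seq_len(n_chrom), each = markers_per)),
    pos_cM = rep(seq(0, len_cM, length.out = markers_per), n_chrom),
    pos_bp = rep(round(seq(1, 1e6, length.out = markers_per)), n_chrom)
  )
}

# construct a trait vector with an exact sample correlation r to the
# genotype codes at `marker` (used to pin LOD values)
trait_with_exact_r <- function(genos, marker, r, seed = 1) {
  G <- geno_matrix(genos)
  g <- G[, marker]
  set.seed(seed)
  z <- rnorm(length(g))
  gs <- (g - mean(g)) / sd(g)
  e <- residuals(lm(z ~ g))
  es <- (e - mean(e)) / sd(e)
  y <- r * gs + sqrt(1 - r^2) * es
  names(y) <- rownames(G)
  y
}

# labelled sorter events with a controllable class gap (animals are dense
# for their length, bubbles thin); gap 0 gives touching classes
bubble_fixture <- function(n_animal = 500, n_bubble = 500, seed = 1,
                           animal_slope = 1.2, bubble_slope = 0.15,
                           noise = 5) {
  set.seed(seed)
  tof_a <- runif(n_animal, 80, 350)
  tof_b <- runif(n_bubble, 100, 1200)
  tibble::tibble(
    plate_id = "p1",
    row = sample(LETTERS[1:8], n_animal + n_bubble, replace = TRUE),
    col = sample(1:12, n_animal + n_bubble, replace = TRUE),
    TOF = c(tof_a, tof_b),
    EXT = pmax(0, c(animal_slope * tof_a + rnorm(n_animal, 0, noise),
                    bubble_slope * tof_b + rnorm(n_bubble, 0, noise))),
    green = 5, yellow = 5, red = 8,
    truth = rep(c("animal", "bubble"), c(n_animal, n_bubble))
  )
}

# study-sized panel: 357 lines on a 1454-marker map, as phenotyped panels of
# this design are; built lazily because only the acceptance-level checks use it
panel_full <- function() {
  fixture("panel_full", function() {
    simulate_cross(cross_design(357, seed = 101), sim_genetic_map(1454))
  })
}
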