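# Shared fixtures: meshes are deterministic and moderately expensive, so
# they are built once per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

fixtureMesh <- function(subdivisions) {
  key <- paste0("mesh", subdivisions)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- buildIcosphere(subdivisions)
  }
  .fixtures[[key]]
}

fixtureNeighborhoods <- function(subdivisions, ring = 2L) {
  key <- paste0("nbh", subdivisions, "_", ring)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- neighborhoodMatrix(fixtureMesh(subdivisions), ring)
  }
  .fixtures[[key]]
}

# A small balanced ANT trial table with exact condition means: correct-trial
# mean RTs 550 (congruent), 600 (incongruent), 575 (neutral) over one test
# block per cell; equal counts make the overall correct mean exactly 575.
handBuiltAntTable <- function() {
  mk <- function(target, rts) {
    data.frame(
      subject_id = "s1", block = 1L, cue = "none", target = target,
      rt_ms = rts, correct = TRUE, stringsAsFactors = FALSE
    )
  }
  rbind(
    mk("congruent", c(540, 550, 560)),
    mk("incongruent", c(590, 600, 610)),
    mk("neutral", c(565, 575, 585))
  )
}

# Independent oracle for Kendall's W on tie-free data: the mean pairwise
# Spearman identity W = ((m - 1) * rbar + 1) / m.
spearmanOracleW <- function(mat) {
  sp <- stats::cor(t(mat), method = "spearman")
  m <- nrow(mat)
  rbar <- mean(sp[lower.tri(sp)])
  ((m - 1) * rbar + 1) / m
}
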