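# Shared fixtures, built once per test run and cached in this environment.
.fix <- new.env(parent = emptyenv())

# small mixed cohort used by several test files
smallCohort <- function() {
  if (is.null(.fix$smallCohort))
    .fix$smallCohort <- generateCohort(
      PhantomConfig(nSubjects = 16, gliomaFraction = 0.5, seed = 301))
  .fix$smallCohort
}

# a quickly trained tiny network on control phantoms (weak but functional)
tinyTrainedBan <- function() {
  if (is.null(.fix$tinyBan)) {
    coh <- generateCohort(
      PhantomConfig(nSubjects = 24, gliomaFraction = 0, seed = 302))
    subj <- subjectTable(coh)
    sp <- list(train = 1:18, val = 19:24)
    cfg <- BanConfig(convChannels = c(2L, 4L), maxEpochs = 2L, seed = 303)
    .fix$tinyBan <- list(
      model = trainBan(cohortVolumes(coh), cohortMasks(coh), subj$age,
                       sp, cfg),
      cohort = coh, splits = sp)
  }
  .fix$tinyBan
}

# one glioma phantom (volume + non-empty mask) in the 32^3 geometry
gliomaPhantom <- function() {
  coh <- smallCohort()
  i <- which(subjectTable(coh)$grade != "none")[1]
  list(volume = cohortVolumes(coh)[[i]], mask = cohortMasks(coh)[[i]])
}

expect_binary_identical <- function(a, b) expect_identical(a, b)
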