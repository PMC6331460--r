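## Shared fixture builders. Everything is generated in code at test time.

smallCohort <- function(seed = 1, n = 40, rho = 0.7, nSalient = 20,
                        grid = c(8, 8, 4), fraction = 0.6) {
  generateCohort(simConfig(nSubjects = n, gridShape = grid,
                           skeletonFraction = fraction,
                           nSalient = nSalient, rho = rho, seed = seed))
}

## linear indices of ground-truth salient voxels within a dataset's columns
salientColumns <- function(cohort) {
  vi <- voxelIndex(cohort$dataset)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  match(key(cohort$truth@salientCoords), key(vi))
}

## rank-based (Mann-Whitney) area under the ROC curve
aucRank <- function(scores, labels) {
  stopifnot(any(labels), any(!labels))
  (mean(rank(scores)[labels]) - (sum(labels) + 1) / 2) / sum(!labels)
}

## write a cohort plus an extra pure-noise score column to disk; returns paths
writeStudyFixture <- function(dir, seed = 42, n = 60, grid = c(10, 10, 4),
                              fraction = 0.5, nSalient = 30, rho = 0.7) {
  cohort <- generateCohort(simConfig(nSubjects = n, gridShape = grid,
                                     skeletonFraction = fraction,
                                     nSalient = nSalient, rho = rho,
                                     seed = seed))
  paths <- writeCohort(cohort, dir)
  tab <- read.csv(paths[["table"]])
  set.seed(seed + 1)
  tab$nullscore <- rnorm(nrow(tab))
  write.csv(tab, paths[["table"]], row.names = FALSE, quote = FALSE)
  list(paths = paths, cohort = cohort)
}
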