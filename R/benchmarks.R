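## The package's standard biased benchmark: the synthetic study conditions
## used by the debiasing demonstrations and the test suite.

#' Standard biased benchmark fixture
#'
#' A ~200-sample synthetic cohort from four source sites with the
#' generator's default batch effects and, by default, a class-correlated
#' site allocation like the original cohort's (sites contribute very
#' different risk mixes, so an undebiased classifier can exploit the site
#' as a shortcut): rows = sites, columns = [riskLevels()].
#'
#' @param seed integer master seed for the generator.
#' @param correlated logical; FALSE gives a balanced allocation
#'   (17 samples per site x risk cell) with the same batch effects.
#' @param images logical; also encode per-sample heatmap images.
#' @return list with `dataset` (a [ScentDataset-class]), `truth`
#'   (generator ground truth), `meta` (the manifest), and `images`
#'   (named list of [ScentImage-class], or NULL).
#' @seealso [simConfig()], [sourceClusteringAudit()], [trainAdversarial()]
#' @export
biasBenchmark <- function(seed = 11L, correlated = TRUE, images = TRUE) {
  alloc <- if (correlated)
    rbind(c(36L, 9L, 6L),
          c(9L, 33L, 9L),
          c(6L, 9L, 36L),
          c(15L, 15L, 15L))
  else 17L
  g <- generateDataset(simConfig(n_per_cell = alloc, seed = seed))
  list(dataset = g$dataset, truth = g$truth, meta = sampleMeta(g$dataset),
       images = if (images) imagifyDataset(g$dataset) else NULL)
}
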