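# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

# default-condition study: 4 genes, ~190 sites, noise SD 10
sharedStudy <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulateStudy(simConfig(), seed = 101)
  .fixture_env$study
}

sharedRecords <- function() {
  if (is.null(.fixture_env$records))
    .fixture_env$records <- processScreen(sharedStudy()$measurements)
  .fixture_env$records
}

# 50-mer consensus windows for the shared panel (NA-free subset flag)
sharedWindows <- function() {
  if (is.null(.fixture_env$windows)) {
    st <- sharedStudy()
    win <- vapply(seq_len(nrow(st$panel)), function(i)
      common50mer(st$genes[[st$panel$gene_id[i]]]$merged,
                  st$panel$start[i])$window, character(1))
    .fixture_env$windows <- win
  }
  .fixture_env$windows
}

# labels for one scaffold/assay joined to the panel order
panelLabels <- function(assay = "reporter", scaffold = "asym_omef") {
  st <- sharedStudy()
  rec <- sharedRecords()
  sub <- rec[rec$assay == assay & rec$scaffold == scaffold, ]
  sub$label[match(st$panel$site_id, sub$site_id)]
}

panelMeans <- function(assay = "reporter", scaffold = "asym_omef") {
  st <- sharedStudy()
  rec <- sharedRecords()
  sub <- rec[rec$assay == assay & rec$scaffold == scaffold, ]
  sub$mean[match(st$panel$site_id, sub$site_id)]
}

# Jaccard index between two interval sets given as data.frames with
# start/end columns (integer positions)
intervalJaccard <- function(a, b) {
  A <- unique(unlist(mapply(seq, a$start, a$end, SIMPLIFY = FALSE)))
  B <- unique(unlist(mapply(seq, b$start, b$end, SIMPLIFY = FALSE)))
  length(intersect(A, B)) / length(union(A, B))
}

randomRnaString <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
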