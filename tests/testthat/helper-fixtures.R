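# Fixture builders used across the suite. Everything is generated in code at
# test time; no data files.

# Small curated-style database: one WNT-like heteromeric receptor and two
# interactions.
toy_db <- function() {
  lr_database(
    genes = c("WNT7A", "FZD5", "LRP6", "JAG1", "NOTCH1", "DLL1"),
    complexes = list(WNT_receptor = c("FZD5", "LRP6")),
    interactions = data.frame(
      interaction_id = c("I_WNT", "I_NOTCH"),
      partner_a = c("WNT7A", "JAG1"),
      partner_b = c("WNT_receptor", "NOTCH1"),
      annotation = c("pathway=WNT", "pathway=NOTCH"),
      stringsAsFactors = FALSE)
  )
}

# Hand-sized count matrix with named cells/genes and no zero-total cells.
toy_counts <- function(n_cells = 30, genes = c("WNT7A", "FZD5", "LRP6",
                                               "JAG1", "NOTCH1", "DLL1"),
                       seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * length(genes), 2), nrow = n_cells,
              dimnames = list(sprintf("cell%03d", seq_len(n_cells)), genes))
  m[, 1] <- m[, 1] + 1  # keep every cell's total positive
  storage.mode(m) <- "double"
  m
}

toy_annot <- function(counts, n_clusters = 3) {
  cl <- rep(paste0("K", seq_len(n_clusters)), length.out = nrow(counts))
  data.frame(cell = rownames(counts), cluster = cl,
             donor = rep(c("d1", "d2"), length.out = nrow(counts)),
             total_counts = unname(rowSums(counts)),
             stringsAsFactors = FALSE)
}

# Random small problem instance for oracle-equivalence testing: counts with
# cluster-structured Poisson signal, a database mixing simple and complex
# partners (sometimes referencing a gene absent from the matrix, which must
# be skipped), and two microenvironments.
random_fixture <- function(seed, max_clusters = 6, max_genes = 120,
                           max_interactions = 30) {
  set.seed(seed)
  k <- sample(2:max_clusters, 1)
  g <- sample(30:max_genes, 1)
  n_per <- sample(8:20, 1)
  genes <- sprintf("g%03d", seq_len(g))
  clusters <- paste0("K", seq_len(k))
  cl <- rep(clusters, each = n_per)
  cells <- sprintf("c%04d", seq_along(cl))
  lam <- rexp(g, rate = 1 / 1.5) + 0.05
  counts <- matrix(rpois(length(cl) * g, rep(lam, each = length(cl))),
                   nrow = length(cl), dimnames = list(cells, genes))
  # plant some cluster-specific enrichment so the DE criterion can fire
  for (i in seq_len(max(3, g %/% 10))) {
    gi <- sample(g, 1); ci <- sample(clusters, 1)
    counts[cl == ci, gi] <- counts[cl == ci, gi] +
      rpois(sum(cl == ci), lam[gi] * runif(1, 2, 5))
  }
  counts[, 1] <- counts[, 1] + 1
  storage.mode(counts) <- "double"
  annot <- data.frame(cell = cells, cluster = cl,
                      donor = "d1", total_counts = unname(rowSums(counts)),
                      stringsAsFactors = FALSE)

  db_genes <- c(genes, "ghostA")  # one gene the matrix never has
  n_cpx <- sample(1:3, 1)
  complexes <- lapply(seq_len(n_cpx), function(i) {
    sample(genes, sample(2:3, 1))
  })
  names(complexes) <- sprintf("CPX%02d", seq_len(n_cpx))
  partners_pool <- c(genes, names(complexes))
  n_ia <- sample(5:max_interactions, 1)
  seen <- character()
  pa <- pb <- character()
  while (length(pa) < n_ia) {
    cand <- sample(partners_pool, 2)
    key <- paste(sort(cand), collapse = "|")
    if (key %in% seen || cand[1] == cand[2]) next
    seen <- c(seen, key)
    pa <- c(pa, cand[1]); pb <- c(pb, cand[2])
  }
  # one interaction touching the ghost gene, to exercise the skip path
  pa <- c(pa, "ghostA"); pb <- c(pb, sample(genes, 1))
  interactions <- data.frame(
    interaction_id = sprintf("ia%03d", seq_along(pa)),
    partner_a = pa, partner_b = pb, annotation = "",
    stringsAsFactors = FALSE)
  db <- lr_database(db_genes, complexes, interactions)

  env_tbl <- do.call(rbind, lapply(c("envA", "envB"), function(e) {
    data.frame(cell_type = sample(clusters, sample(2:k, 1)),
               microenvironment = e, stringsAsFactors = FALSE)
  }))
  envs <- load_microenvironments(env_tbl)
  list(counts = counts, annot = annot, db = db, envs = envs)
}

# exit status of a system2() capture: NULL attribute means success (0)
exit_status <- function(x) {
  s <- attr(x, "status")
  if (is.null(s)) 0L else s
}
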