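# Shared helpers: in-memory expression tables, tiny genomes/tracks, a
# cached small fixture bundle, and the scikit-learn reference LARS runner.

# Build an expression_table directly from a matrix and metadata.
make_expr <- function(fpkm, condition, up_condition = condition[1L],
                      protein = TRUE, de = TRUE,
                      gene_id = NULL) {
  n <- nrow(fpkm)
  if (is.null(rownames(fpkm)))
    rownames(fpkm) <- sprintf("iso%03d", seq_len(n))
  colnames(fpkm) <- paste0(condition, "_", stats::ave(seq_along(condition),
                                                      condition,
                                                      FUN = seq_along))
  info <- data.frame(
    isoform_id = rownames(fpkm),
    gene_id = gene_id %||% sprintf("G%03d", seq_len(n)),
    protein_evidence = rep_len(protein, n),
    de_flag = rep_len(de, n),
    up_condition = rep_len(up_condition, n),
    stringsAsFactors = FALSE)
  structure(list(info = info, fpkm = fpkm, condition = condition),
            class = "expression_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a per-base bedGraph for a score vector and load it as a cons_track.
make_track <- function(scores, chrom = "chr1", offset = 0L) {
  f <- tempfile(fileext = ".bedGraph")
  n <- length(scores)
  writeLines(sprintf("%s\t%d\t%d\t%.6f", chrom, offset + 0:(n - 1L),
                     offset + 1:n, scores), f)
  read_conservation(f)
}

# A DNAStringSet genome from plain strings.
make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

# Deterministic random DNA string.
random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small full fixture bundle, generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())
shared_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    cfg <- fixture_config(seed = 11, n_groups = 2, group_sizes = c(10L, 12L),
                          n_isoforms = 25L, n_tfs = 8L, n_sfs = 5L,
                          true_support_per_group = 3L)
    .fixture_cache$fx <- generate_fixture(cfg, file.path(tempdir(),
                                                         "tsnet_shared_fx"))
  }
  .fixture_cache$fx
}

# Standardized random regression design.
random_design <- function(n, p, seed, sparse_beta = NULL, noise = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- if (is.null(sparse_beta)) rnorm(n, sd = noise) else
    drop(x %*% sparse_beta) + rnorm(n, sd = noise)
  standardize(x, y)
}

# Reference LARS paths from scikit-learn (one python invocation for all
# designs).  Each design is a list(x = standardized matrix, y = centered
# response); returns a list of breakpoint coefficient matrices.
sklearn_lars_paths <- function(designs) {
  dir <- tempfile("sklars")
  dir.create(dir)
  for (i in seq_along(designs)) {
    utils::write.table(designs[[i]]$x, file.path(dir, sprintf("X%03d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(designs[[i]]$y, file.path(dir, sprintf("y%03d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  script <- file.path(dir, "ref_lars.py")
  writeLines(c(
    "import sys, glob",
    "import numpy as np",
    "from sklearn.linear_model import lars_path",
    "d = sys.argv[1]",
    "for xf in sorted(glob.glob(d + '/X*.csv')):",
    "    i = xf[-7:-4]",
    "    X = np.loadtxt(xf, delimiter=',', ndmin=2)",
    "    y = np.loadtxt(d + '/y' + i + '.csv', delimiter=',')",
    "    alphas, active, coefs = lars_path(X, y, method='lar')",
    "    np.savetxt(d + '/coefs' + i + '.csv', coefs.T, delimiter=',')",
    "    np.savetxt(d + '/alphas' + i + '.csv', alphas, delimiter=',')"),
    script)
  status <- system2("python", c(script, dir), stdout = TRUE, stderr = TRUE)
  out <- lapply(seq_along(designs), function(i) {
    f <- file.path(dir, sprintf("coefs%03d.csv", i))
    if (!file.exists(f))
      stop("reference LARS run failed: ", paste(status, collapse = "\n"))
    list(coefs = as.matrix(utils::read.csv(f, header = FALSE)),
         alphas = as.numeric(readLines(file.path(dir,
                                                 sprintf("alphas%03d.csv",
                                                         i)))))
  })
  out
}
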