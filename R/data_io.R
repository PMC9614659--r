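## Readers/writers for the four TSV input dialects and all result artifacts.
## Canonical dialect: UTF-8 TSV with a header row; lines starting with '#'
## are comments. Validation errors name the file, line and offending id.

.readTsv <- function(path, columns) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop(sprintf("%s: empty file", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[seq_along(columns)], columns))
    stop(sprintf("%s: expected header '%s', found '%s'", path,
                 paste(columns, collapse = "\t"), lines[1]))
  body <- lines[-1]; lineNo <- lineNo[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nc <- lengths(parts)
  bad <- which(nc != length(columns))
  if (length(bad))
    stop(sprintf("%s: line %d has %d column(s), expected %d", path,
                 lineNo[bad[1]], nc[bad[1]], length(columns)))
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- columns
  attr(out, "lineNo") <- lineNo
  out
}

#' Read the four TSV input dialects
#'
#' `readAssociations`: columns `mirna_id`, `disease_id` (presence = 1).
#' `readTreeNumbers`: columns `disease_id`, `tree_number`.
#' `readGeneNetwork`: columns `gene_a`, `gene_b`, `lls` (raw real score).
#' `readMirnaTargets`: columns `mirna_id`, `gene_id`.
#'
#' @param path TSV file path.
#' @return data.frame of the parsed records.
#' @name readers
NULL

#' @rdname readers
#' @export
readAssociations <- function(path) .readTsv(path, c("mirna_id", "disease_id"))

#' @rdname readers
#' @export
readTreeNumbers <- function(path) .readTsv(path, c("disease_id", "tree_number"))

#' @rdname readers
#' @export
readGeneNetwork <- function(path) {
  out <- .readTsv(path, c("gene_a", "gene_b", "lls"))
  lls <- suppressWarnings(as.numeric(out$lls))
  bad <- which(is.na(lls))
  if (length(bad))
    stop(sprintf("%s: line %d: non-numeric lls for pair (%s, %s)", path,
                 attr(out, "lineNo")[bad[1]], out$gene_a[bad[1]],
                 out$gene_b[bad[1]]))
  out$lls <- lls
  out
}

#' @rdname readers
#' @export
readMirnaTargets <- function(path) .readTsv(path, c("mirna_id", "gene_id"))

#' Load and validate the four inputs into a dataset
#'
#' Applies the upstream filtering rule: microRNAs without target genes and
#' diseases without hierarchy positions are removed, then associations
#' referencing removed entities are dropped. Duplicate association rows are
#' deduplicated with a warning. Counts before/after are logged.
#'
#' @param associations,treeNumbers,geneNetwork,targets file paths.
#' @return an [MDADataset-class].
#' @export
loadDataset <- function(associations, treeNumbers, geneNetwork, targets) {
  assoc <- readAssociations(associations)
  tree <- readTreeNumbers(treeNumbers)
  gene <- readGeneNetwork(geneNetwork)
  tgt <- readMirnaTargets(targets)

  dup <- duplicated(assoc)
  if (any(dup)) {
    warning(sprintf("%s: %d duplicate association row(s) deduplicated",
                    associations, sum(dup)))
    assoc <- assoc[!dup, ]
  }
  mirnas <- sort(unique(assoc$mirna_id))
  diseases <- sort(unique(assoc$disease_id))
  mdaLog("loadDataset: %d associations, %d miRNAs, %d diseases before filtering",
         nrow(assoc), length(mirnas), length(diseases))

  withTargets <- unique(tgt$mirna_id)
  withTree <- unique(tree$disease_id)
  dropM <- setdiff(mirnas, withTargets)
  dropD <- setdiff(diseases, withTree)
  if (length(dropM))
    mdaLog("loadDataset: removed %d miRNA(s) without target genes (%s)",
           length(dropM), paste(utils::head(dropM, 5), collapse = ", "))
  if (length(dropD))
    mdaLog("loadDataset: removed %d disease(s) without hierarchy (%s)",
           length(dropD), paste(utils::head(dropD, 5), collapse = ", "))
  keepM <- setdiff(mirnas, dropM)
  keepD <- setdiff(diseases, dropD)
  drop <- !(assoc$mirna_id %in% keepM & assoc$disease_id %in% keepD)
  if (any(drop))
    warning(sprintf("dropped %d association(s) referencing removed entities",
                    sum(drop)))
  assoc <- assoc[!drop, ]
  if (!nrow(assoc)) stop("no associations left after filtering")

  X <- AssociationMatrix(assoc, mirnas = keepM, diseases = keepD)
  dag <- buildDiseaseDAG(tree)
  net <- normalizeLLS(gene)
  targetList <- lapply(split(tgt$gene_id, tgt$mirna_id), unique)
  mdaLog("loadDataset: %d associations, %d miRNAs, %d diseases after filtering",
         sum(X@values), length(keepM), length(keepD))
  new("MDADataset", associations = X, dag = dag, geneNet = net,
      targets = targetList,
      provenance = list(paths = c(associations = associations,
                                  treeNumbers = treeNumbers,
                                  geneNetwork = geneNetwork,
                                  targets = targets),
                        rows = c(associations = nrow(assoc),
                                 treeNumbers = nrow(tree),
                                 geneNetwork = nrow(gene),
                                 targets = nrow(tgt))))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a similarity or score matrix as square TSV
#'
#' Full square form with an id header row and an `id` first column; numeric
#' values carry 12 significant digits so a read-back reproduces the matrix to
#' within 1e-12.
#'
#' @param M matrix (or [SimilarityMatrix-class]) with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMatrixTsv <- function(M, path) {
  M <- as.matrix(M)
  df <- data.frame(id = rownames(M),
                   signif(M, 12), check.names = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' Read back a matrix written by [writeMatrixTsv()]
#'
#' @param path TSV path.
#' @return numeric matrix with dimnames.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}

#' Write the four fixture input files
#'
#' @param fixture output of [synthFixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    associations = .writeTsv(fixture$assocRecords, file.path(dir, "associations.tsv")),
    treeNumbers = .writeTsv(fixture$treeRecords, file.path(dir, "tree_numbers.tsv")),
    geneNetwork = .writeTsv(transform(fixture$geneRecords, lls = signif(lls, 12)),
                            file.path(dir, "gene_network.tsv")),
    targets = .writeTsv(fixture$targetRecords, file.path(dir, "mirna_targets.tsv")))
  gt <- data.frame(mirna_id = rep(rownames(fixture$clean), ncol(fixture$clean)),
                   disease_id = rep(colnames(fixture$clean),
                                    each = nrow(fixture$clean)),
                   clean = as.vector(fixture$clean))
  paths <- c(paths, groundTruth = .writeTsv(gt, file.path(dir, "ground_truth.tsv")))
  paths
}

#' Write prediction and evaluation outputs
#'
#' Writes whichever artifacts are supplied: the square score matrix, the
#' long-form score table (sorted by descending score, with known flags), the
#' per-fold CV table, the solver trace, and a YAML echo of the configuration.
#'
#' @param dir output directory.
#' @param scores optional miRNA x disease score matrix.
#' @param X optional [AssociationMatrix-class] for the known flags.
#' @param cv optional result of [runCV()].
#' @param fit optional [BNNRFit-class] for the solver trace.
#' @param config optional named list echoed to `config.yaml`.
#' @return named character vector (manifest) of written paths.
#' @export
writeOutputs <- function(dir, scores = NULL, X = NULL, cv = NULL, fit = NULL,
                         config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("cannot create output directory %s", dir))
  manifest <- character(0)
  if (!is.null(scores)) {
    manifest["scoreMatrix"] <- writeMatrixTsv(scores, file.path(dir, "scores.tsv"))
    long <- data.frame(
      mirna_id = rep(rownames(scores), ncol(scores)),
      disease_id = rep(colnames(scores), each = nrow(scores)),
      score = signif(as.vector(scores), 12),
      known_flag = if (!is.null(X)) as.integer(as.vector(X@values)) else NA_integer_)
    long <- long[order(-long$score, long$mirna_id, long$disease_id), ]
    manifest["scoreTable"] <- .writeTsv(long, file.path(dir, "scores_long.tsv"))
  }
  if (!is.null(cv)) {
    tab <- cv$folds
    names(tab)[names(tab) == "repeatIndex"] <- "repeat"
    manifest["cvTable"] <- .writeTsv(tab, file.path(dir, "cv_auc.tsv"))
  }
  if (!is.null(fit)) {
    tr <- solverTrace(fit)
    tr$relChange <- signif(tr$relChange, 12)
    tr$gap <- signif(tr$gap, 12)
    manifest["trace"] <- .writeTsv(tr, file.path(dir, "solver_trace.tsv"))
  }
  if (!is.null(config)) {
    manifest["config"] <- file.path(dir, "config.yaml")
    writeRunConfig(config, manifest["config"])
  }
  manifest
}

#' Default run configuration
#'
#' All tunables in one list, with the method's standard values: decay
#' `delta = 0.5`, fusion weight `w = 0.3`, kernel multiplier
#' `gammaPrime = 0.5`, solver `alpha = 1`, `beta = 10`, `tol = 1e-6`,
#' `maxIter = 300`, and 5-fold x 10-repeat cross validation.
#'
#' @param ... overrides of individual fields.
#' @return named list.
#' @export
runConfig <- function(...) {
  cfg <- list(delta = 0.5, w = 0.3, gammaPrime = 0.5, alpha = 1, beta = 10,
              tol = 1e-6, maxIter = 300L, nFolds = 5L, nRepeats = 10L,
              seed = 42L, outDir = "results")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param config list from [runConfig()].
#' @param path YAML file path.
#' @return `writeRunConfig` the path invisibly; `readRunConfig` the
#'   round-tripped list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$maxIter <- as.integer(cfg$maxIter)
  cfg$nFolds <- as.integer(cfg$nFolds)
  cfg$nRepeats <- as.integer(cfg$nRepeats)
  cfg$seed <- as.integer(cfg$seed)
  do.call(runConfig, cfg)
}
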