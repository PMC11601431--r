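# Experimental pKa tables, leakage-free stratified splits and conformer
# augmentation.
#
# Records follow the PKAD-style delimited layout. The unit of data
# splitting is the *unique residue* (protein accession + residue number +
# mutation tag + conformational state): every measurement and every
# structure of one unique residue always travels to the same side of a
# split, which is what prevents train/test leakage.

PKAD_MANDATORY_COLS <- c("protein", "aa", "resid", "pka")

#' Read a PKAD-style pKa table
#'
#' Accepts comma- or tab-delimited files with a header. Mandatory columns:
#' `protein` (accession), `aa` (3-letter residue type), `resid` (author
#' residue number), `pka`. Optional: `chain` (default "A"), `mutation`
#' (default "WT"), `state` (conformational state, default "S1", treated as
#' an opaque tag), `structures` (semicolon-separated structure ids).
#' Rows whose pKa does not parse as a finite number in [0, 16] -- e.g.
#' values given as ranges like ">9" -- are skipped with a warning and
#' counted in the `skipped` attribute.
#'
#' @param file path to the delimited table.
#' @return data.frame of class `pka_records`, one row per measurement,
#'   with a derived `unique_key` column; multiple measurements of one
#'   residue share a `unique_key`.
#' @export
read_pkad_table <- function(file) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  missing_cols <- setdiff(PKAD_MANDATORY_COLS, names(df))
  if (length(missing_cols))
    stop("pKa table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (is.null(df$chain)) df$chain <- "A"
  if (is.null(df$mutation)) df$mutation <- "WT"
  if (is.null(df$state)) df$state <- "S1"
  if (is.null(df$structures)) df$structures <- ""
  df$aa <- toupper(df$aa)

  pka <- suppressWarnings(as.numeric(df$pka))
  bad <- is.na(pka) | !is.finite(pka) | pka < 0 | pka > 16
  if (any(bad))
    warning(sprintf("skipped %d row(s) with unparseable or out-of-range pKa (e.g. %s)",
                    sum(bad), df$pka[which(bad)[1]]))
  df <- df[!bad, , drop = FALSE]
  df$pka <- pka[!bad]
  bad_aa <- !(df$aa %in% TITRATABLE_AA)
  if (any(bad_aa)) {
    warning(sprintf("skipped %d row(s) with non-titratable residue type", sum(bad_aa)))
    df <- df[!bad_aa, , drop = FALSE]
  }
  df$unique_key <- paste(df$protein, df$resid, df$mutation, df$state, sep = "|")
  rownames(df) <- NULL
  attr(df, "skipped") <- sum(bad) + sum(bad_aa)
  class(df) <- c("pka_records", "data.frame")
  df
}

#' Structure references of each record
#'
#' @param records a `pka_records` data.frame.
#' @return list of character vectors (split on ";"), one per row.
#' @export
record_structures <- function(records) {
  if (nrow(records) == 0L) return(list())
  strsplit(ifelse(is.na(records$structures), "", records$structures), ";",
           fixed = TRUE)
}

#' Partition records into acidic and basic residues
#'
#' Acids: Asp, Glu, Cys, Tyr. Bases: His, Lys. The distinct mechanisms of
#' their pKa shifts (burial protonates acids but deprotonates bases) are
#' why separate regression models are trained per partition.
#'
#' @param records a `pka_records` data.frame.
#' @return list with elements `acid` and `base`, an exhaustive disjoint
#'   partition of the rows.
#' @export
partition_acid_base <- function(records) {
  list(acid = records[records$aa %in% ACID_AA, , drop = FALSE],
       base = records[records$aa %in% BASE_AA, , drop = FALSE])
}

#' Stratified unique-residue train/test splits
#'
#' Draws `n_splits` independent random partitions of the unique residue
#' keys into ~(1 - test_fraction) train / test_fraction test, stratified
#' over quantile bins of the per-key mean pKa so the train and test label
#' distributions match. All measurements and structures of a key travel
#' together. Per-split seeds are spawned deterministically from the master
#' seed (`sample.int(.Machine$integer.max, n_splits)` after
#' `set.seed(seed)`).
#'
#' @param records a `pka_records` data.frame (>= 20 unique keys).
#' @param n_splits number of holdout splits (paper protocol: 20).
#' @param test_fraction fraction of keys held out per split.
#' @param seed master seed.
#' @param n_bins number of pKa quantile strata (bins too small to split
#'   are merged with a warning).
#' @return object of class `split_plan`: list with `n_splits`,
#'   `test_fraction`, `seed` and `splits`, each split a list of disjoint
#'   `train` / `test` key vectors covering all keys.
#' @export
make_splits <- function(records, n_splits = 20L, test_fraction = 0.10,
                        seed = 1L, n_bins = 5L) {
  keys <- unique(records$unique_key)
  if (length(keys) < 20L)
    stop("need at least 20 unique keys to form splits")
  key_pka <- tapply(records$pka, records$unique_key, mean)[keys]

  qs <- stats::quantile(key_pka, probs = seq(0, 1, length.out = n_bins + 1L))
  qs <- unique(qs)
  if (length(qs) - 1L < n_bins)
    warning("degenerate pKa quantiles: strata merged")
  bin <- cut(key_pka, breaks = qs, include.lowest = TRUE, labels = FALSE)
  # merge strata too small to contribute at least one test key
  tb <- table(bin)
  small <- as.integer(names(tb)[tb * test_fraction < 1])
  if (length(small) && length(tb) > 1L) {
    warning("merging ", length(small), " small stratum/strata")
    bin[bin %in% small] <- max(bin)
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max, n_splits)

  splits <- lapply(seq_len(n_splits), function(s) {
    set.seed(split_seeds[s])
    test <- character(0)
    for (b in sort(unique(bin))) {
      kb <- keys[bin == b]
      n_test <- max(1L, round(test_fraction * length(kb)))
      test <- c(test, sample(kb, n_test))
    }
    list(train = setdiff(keys, test), test = test)
  })
  structure(list(n_splits = n_splits, test_fraction = test_fraction,
                 seed = seed, splits = splits, keys = keys),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  nt <- vapply(x$splits, function(s) length(s$test), integer(1))
  cat(sprintf("<split_plan: %d splits of %d keys, test sizes %d-%d, seed %d>\n",
              x$n_splits, length(x$keys), min(nt), max(nt), x$seed))
  invisible(x)
}

#' Conformer augmentation policy
#'
#' Training residues whose experimental pKa is shifted from the model pKa
#' by more than `shift_threshold` units gain up to `max_conformers` extra
#' training instances from alternative structural models (AlphaFold-style
#' conformers), each carrying the original label.
#'
#' @param shift_threshold absolute pKa-shift threshold (default 2).
#' @param max_conformers cap on added conformers per record (default 10).
#' @export
augmentation_policy <- function(shift_threshold = 2.0, max_conformers = 10L) {
  stopifnot(shift_threshold > 0, max_conformers >= 1)
  structure(list(shift_threshold = shift_threshold,
                 max_conformers = max_conformers),
            class = "augmentation_policy")
}

#' Augment a training set with conformers of highly shifted residues
#'
#' Applied strictly after splitting and only to training records: test
#' keys never gain conformers, so augmentation cannot leak across a split.
#'
#' @param train_records training rows of a `pka_records` data.frame.
#' @param conformer_source either a named list mapping `unique_key` to a
#'   character vector of conformer structure ids, or a
#'   `function(unique_key)` returning such a vector (empty / NULL when no
#'   conformers are available, in which case the record is kept
#'   unaugmented).
#' @param policy an [augmentation_policy()].
#' @return `pka_records` data.frame: the original rows plus one row per
#'   added conformer, flagged by the logical `augmented` column and with
#'   `structures` set to the conformer id.
#' @export
augment_training <- function(train_records, conformer_source,
                             policy = augmentation_policy()) {
  get_conf <- if (is.function(conformer_source)) conformer_source
              else function(k) conformer_source[[k]]
  shift <- abs(train_records$pka - model_pka(train_records$aa))
  out <- train_records
  out$augmented <- FALSE
  extra <- list()
  for (i in which(shift > policy$shift_threshold)) {
    conf <- get_conf(train_records$unique_key[i])
    if (is.null(conf) || length(conf) == 0L) next
    conf <- conf[seq_len(min(length(conf), policy$max_conformers))]
    rows <- train_records[rep(i, length(conf)), , drop = FALSE]
    rows$structures <- conf
    rows$augmented <- TRUE
    extra[[length(extra) + 1L]] <- rows
  }
  if (length(extra)) out <- rbind(out, do.call(rbind, extra))
  rownames(out) <- NULL
  class(out) <- c("pka_records", "data.frame")
  out
}

#' Per-amino-acid summary of a pKa table
#'
#' @param records a `pka_records` data.frame.
#' @return data.frame with one row per amino acid (plus a `Total` row):
#'   `residues` (unique keys), `pkas` (measurements), `structures`
#'   (distinct structure ids).
#' @export
summarize_table <- function(records) {
  out <- lapply(TITRATABLE_AA, function(a) {
    r <- records[records$aa == a, , drop = FALSE]
    strs <- unique(unlist(record_structures(r)))
    strs <- strs[nzchar(strs)]
    data.frame(aa = a, residues = length(unique(r$unique_key)),
               pkas = nrow(r), structures = length(strs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  total_strs <- unique(unlist(record_structures(records)))
  out <- rbind(out, data.frame(aa = "Total",
                               residues = sum(out$residues),
                               pkas = sum(out$pkas),
                               structures = length(total_strs[nzchar(total_strs)])))
  rownames(out) <- NULL
  out
}

#' Published per-amino-acid statistics of the PKAD-2 / PKAD-3 databases
#'
#' The printed database statistics (unique residues, measured pKa's, PDB
#' entries per amino acid) used as reference inputs for partition and
#' growth arithmetic.
#'
#' @return data.frame with one row per amino acid and columns
#'   res2/pka2/pdb2 (PKAD-2) and res3/pka3/pdb3 (PKAD-3).
#' @export
pkad_reference_counts <- function() {
  data.frame(
    aa = c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS"),
    res2 = c(175L, 218L, 116L, 20L, 19L, 67L),
    pka2 = c(214L, 258L, 170L, 20L, 20L, 81L),
    pdb2 = c(403L, 447L, 243L, 20L, 22L, 151L),
    res3 = c(291L, 342L, 155L, 57L, 38L, 109L),
    pka3 = c(330L, 382L, 219L, 60L, 39L, 137L),
    pdb3 = c(520L, 580L, 293L, 62L, 41L, 216L),
    stringsAsFactors = FALSE
  )
}

#' Expand reference per-amino-acid counts into a skeleton record table
#'
#' Builds a `pka_records` table realizing given (residues, pkas,
#' structures) counts per amino acid: each unique residue gets one key,
#' extra measurements are assigned round-robin, and structure ids are
#' distributed round-robin across measurements. Labels are set to the
#' model pKa of the type (the skeleton carries counts, not chemistry).
#'
#' @param counts data.frame with columns `aa`, `residues`, `pkas`,
#'   `structures` (e.g. a renamed slice of [pkad_reference_counts()]).
#' @return a `pka_records` data.frame whose [summarize_table()] reproduces
#'   the input counts.
#' @export
expand_reference_table <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    aa <- counts$aa[i]
    n_res <- counts$residues[i]
    n_pka <- counts$pkas[i]
    n_pdb <- counts$structures[i]
    stopifnot(n_pka >= n_res, n_pdb >= n_pka)
    key_idx <- c(seq_len(n_res),
                 rep_len(seq_len(n_res), n_pka - n_res))
    pdb_ids <- sprintf("%s_pdb%04d", tolower(aa), seq_len(n_pdb))
    pdb_of_row <- split(pdb_ids, rep_len(seq_len(n_pka), n_pdb))
    data.frame(
      protein = sprintf("%s_prot%04d", tolower(aa), key_idx),
      aa = aa, resid = key_idx, chain = "A", mutation = "WT", state = "S1",
      pka = model_pka(aa),
      structures = vapply(seq_len(n_pka),
                          function(j) paste(pdb_of_row[[j]], collapse = ";"),
                          character(1)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$unique_key <- paste(df$protein, df$resid, df$mutation, df$state, sep = "|")
  rownames(df) <- NULL
  class(df) <- c("pka_records", "data.frame")
  df
}
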