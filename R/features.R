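# Full 57-value feature vector for one record. `sass_tables` may be NULL
# when with_structure is FALSE; structure features are then zero.
extract_one <- function(id, sequence, structure, mfe, hexamer_table,
                        sass_tables, with_structure) {
  L <- nchar(sequence)
  orfs <- find_typed_orfs(sequence)

  sif <- c(
    gc_content = gc_content(sequence),
    fickett = fickett_score(sequence),
    orf_length_coverage_features(orfs, L),
    hexamer_transcript = hexamer_score_transcript(sequence, hexamer_table),
    hexamer_score_orf(orfs, hexamer_table),
    rcb_t0 = relative_codon_bias(if (is.null(orfs$t0)) NULL else orfs$t0$sequence),
    rcb_t1 = relative_codon_bias(if (is.null(orfs$t1)) NULL else orfs$t1$sequence),
    rcb_t2 = relative_codon_bias(if (is.null(orfs$t2)) NULL else orfs$t2$sequence),
    rcb_t3 = relative_codon_bias(if (is.null(orfs$t3)) NULL else orfs$t3$sequence)
  )

  if (with_structure) {
    pair <- parse_dotbracket(structure)
    loops <- decompose_loops(pair)
    ssf <- c(
      mfe = if (is.na(mfe)) 0 else mfe,
      paired_ratio = paired_ratio(pair),
      n_hairpin = loops$n_hairpin, n_interior = loops$n_interior,
      n_bulge = loops$n_bulge, n_multi = loops$n_multi,
      c_hairpin = loops$n_hairpin / L, c_interior = loops$n_interior / L,
      c_bulge = loops$n_bulge / L, c_multi = loops$n_multi / L,
      gc_paired = gc_content_paired(sequence, pair),
      vapply(1:5, function(k) {
        sass_score(sequence, structure, k, sass_tables[[paste0("k", k)]])
      }, numeric(1)) |> setNames(paste0("sass_k", 1:5))
    )
  } else {
    ssf <- setNames(rep(0, length(SSF_FEATURES)), SSF_FEATURES)
  }

  c(sif, ssf, protein_features(orfs))[FULL_57]
}

#' Assemble the feature matrix for a set of transcripts
#'
#' Computes the feature vector of every record, in input order, and returns
#' the columns named by the chosen schema subset. Extraction is
#' deterministic and per-record independent, so multithreaded runs produce
#' bit-identical matrices to single-threaded ones.
#'
#' @param records A transcript tibble (filtered; with structures when
#'   `with_structure = TRUE`).
#' @param hexamer_table A hexamer table from [build_hexamer_table()].
#' @param sass_tables SASS tables from [build_sass_tables()] (required when
#'   `with_structure = TRUE`).
#' @param subset Schema subset name, see [feature_schema()].
#' @param with_structure Compute secondary-structure features? When
#'   `FALSE`, SSF columns are zero and provided structures are ignored;
#'   pair this with the `"no_ssf22"` subset for structure-free models.
#' @param threads Number of worker processes for per-record extraction
#'   (forked via the parallel package; results are merged in input order).
#' @return A tibble with column `id` followed by the schema's feature
#'   columns, one row per record.
#' @export
extract_features <- function(records, hexamer_table, sass_tables = NULL,
                             subset = "full57", with_structure = TRUE,
                             threads = 1L) {
  schema <- feature_schema(subset)
  if (with_structure) {
    missing <- is.na(records$structure)
    if (any(missing)) {
      stop("record(s) without structure: ",
           paste(head(records$id[missing], 5L), collapse = ", "),
           if (sum(missing) > 5L) ", ..." else "",
           "; fold them or use with_structure = FALSE", call. = FALSE)
    }
    if (is.null(sass_tables)) {
      stop("sass_tables are required when with_structure = TRUE", call. = FALSE)
    }
  }
  worker <- function(i) {
    extract_one(records$id[[i]], records$sequence[[i]], records$structure[[i]],
                records$mfe[[i]], hexamer_table, sass_tables, with_structure)
  }
  idx <- seq_len(nrow(records))
  rows <- if (threads > 1L && requireNamespace("parallel", quietly = TRUE) &&
              .Platform$OS.type == "unix") {
    parallel::mclapply(idx, worker, mc.cores = threads)
  } else {
    lapply(idx, worker)
  }
  if (length(rows) == 0L) {
    mat <- matrix(numeric(0), nrow = 0, ncol = length(schema),
                  dimnames = list(NULL, schema))
  } else {
    mat <- do.call(rbind, rows)[, schema, drop = FALSE]
  }
  dplyr::bind_cols(tibble(id = records$id), as_tibble(mat))
}
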