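# Monoisotopic masses of the elements handled by formula_mass().
.monoisotopic <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069)

# Mass of the proton; added to the neutral mass for the [M+H]+ adduct.
.proton_mass <- 1.007276

#' Monoisotopic mass of an elemental formula
#'
#' Supports C/H/N/O/P/S formulas such as `"C7H15NO3"`.
#'
#' @param formula Character vector of formulas.
#' @return Neutral monoisotopic masses in Daltons.
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- stringr::str_match_all(f, "([A-Z][a-z]?)([0-9]*)")[[1]]
    m <- m[m[, 2] != "", , drop = FALSE]
    el <- m[, 2]
    cnt <- ifelse(m[, 3] == "", 1L, as.integer(m[, 3]))
    if (any(!el %in% names(.monoisotopic))) {
      abort(sprintf("unsupported element in formula '%s'", f))
    }
    if (sum(nchar(el)) + sum(nchar(m[, 3])) != nchar(f)) {
      abort(sprintf("could not parse formula '%s'", f))
    }
    sum(.monoisotopic[el] * cnt)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Construct a pathway reference
#'
#' @param metabolites Tibble `(metabolite, formula, neutral_mass)`.
#' @param pathways Tibble `(pathway, metabolite)` membership pairs.
#' @param edges Tibble `(from, to)` metabolite adjacency (shared-reaction
#'   links) used to form activity-network modules.
#' @return A `pathway_reference` object.
#' @export
pathway_reference <- function(metabolites, pathways, edges) {
  metabolites <- as_tibble(metabolites)
  pathways <- as_tibble(pathways)
  edges <- as_tibble(edges)
  stopifnot(all(c("metabolite", "neutral_mass") %in% names(metabolites)),
            all(c("pathway", "metabolite") %in% names(pathways)),
            all(c("from", "to") %in% names(edges)))
  if (any(metabolites$neutral_mass <= 0)) abort("neutral masses must be > 0")
  unknown <- setdiff(pathways$metabolite, metabolites$metabolite)
  if (length(unknown)) {
    abort(paste0("pathway members missing from metabolite list: ",
                 paste(utils::head(unknown, 3), collapse = ", ")))
  }
  unknown_e <- setdiff(c(edges$from, edges$to), metabolites$metabolite)
  if (length(unknown_e)) abort("edge endpoints missing from metabolite list")
  structure(list(metabolites = metabolites, pathways = pathways, edges = edges),
            class = "pathway_reference")
}

#' Load a pathway reference from a directory of delimited files
#'
#' Expects `metabolites.csv` (metabolite, formula, neutral_mass),
#' `pathways.csv` (pathway, metabolite) and `edges.csv` (from, to).
#'
#' @param dir Directory path.
#' @export
load_pathway_reference <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  pathway_reference(rd("metabolites.csv"), rd("pathways.csv"), rd("edges.csv"))
}

#' Load the bundled synthetic toy pathway reference
#'
#' A small hand-built reference (carnitine shuttle, vitamin E, kynurenine and
#' monosaccharide metabolism) with formula-derived monoisotopic masses and a
#' shared-reaction adjacency. It is synthetic: pathway memberships follow
#' textbook biochemistry but the set is deliberately tiny, for tests and
#' demonstrations only.
#'
#' @export
load_toy_reference <- function() {
  load_pathway_reference(system.file("extdata", "toy_reference",
                                     package = "frailmet", mustWork = TRUE))
}

#' @export
print.pathway_reference <- function(x, ...) {
  cat(sprintf("Pathway reference: %d metabolites, %d pathways, %d edges\n",
              nrow(x$metabolites), length(unique(x$pathways$pathway)),
              nrow(x$edges)))
  invisible(x)
}

#' Annotate feature m/z values against a pathway reference
#'
#' A feature matches a metabolite when its observed m/z lies within `tol_ppm`
#' of the metabolite's \[M+H\]+ value (neutral mass + 1.007276 Da). One
#' feature may hit several metabolites and vice versa; all matches are
#' returned.
#'
#' @param features Tibble `(feature, mz)` or a feature table whose column
#'   names encode m/z (see [feature_info()]).
#' @param reference A [pathway_reference()].
#' @param tol_ppm Mass tolerance in parts per million (> 0).
#' @return Tibble `(feature, mz, metabolite, adduct, ppm_error)`.
#' @export
annotate_mz <- function(features, reference, tol_ppm = 10) {
  if (tol_ppm <= 0) abort("`tol_ppm` must be > 0")
  if (!inherits(reference, "pathway_reference")) abort("`reference` must be a pathway_reference")
  if (nrow(reference$metabolites) == 0) abort("empty reference")
  features <- as_tibble(features)
  if (!all(c("feature", "mz") %in% names(features))) features <- feature_info(features)
  theo <- reference$metabolites$neutral_mass + .proton_mass
  hits <- lapply(seq_len(nrow(features)), function(i) {
    err <- (features$mz[i] - theo) / theo * 1e6
    j <- which(abs(err) <= tol_ppm)
    if (!length(j)) return(NULL)
    tibble(feature = features$feature[i], mz = features$mz[i],
           metabolite = reference$metabolites$metabolite[j],
           adduct = "[M+H]+", ppm_error = err[j])
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble(feature = character(), mz = numeric(),
                  metabolite = character(), adduct = character(),
                  ppm_error = numeric())
  }
  out
}

#' Score pathway activity from annotated significant features
#'
#' Mummichog-style enrichment: a pathway's observed overlap is the number of
#' member metabolites hit by at least one significant feature. The null draws
#' `n_perm` random feature sets of the same size from the full feature list,
#' re-annotates, and recomputes the overlap;
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`. Each metabolite's evidence
#' score is the number of distinct significant features annotating it.
#'
#' @param hits Annotation of **all** features, from [annotate_mz()].
#' @param significant Character vector of significant feature ids (subset of
#'   `all_features`).
#' @param all_features Character vector: the full feature universe.
#' @param reference A [pathway_reference()].
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A `pathway_scores` object: `scores` (tibble: pathway, size,
#'   overlap, expected, p), `evidence` (tibble: metabolite, evidence).
#' @export
score_pathways <- function(hits, significant, all_features, reference,
                           n_perm = 199, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 99L)
  if (!all(significant %in% all_features)) {
    abort("`significant` must be a subset of `all_features`")
  }
  paths <- split(reference$pathways$metabolite, reference$pathways$pathway)
  met_by_feature <- split(hits$metabolite, hits$feature)

  overlap_of <- function(feat_set) {
    mets <- unique(unlist(met_by_feature[intersect(feat_set, names(met_by_feature))],
                          use.names = FALSE))
    vapply(paths, function(m) sum(m %in% mets), integer(1))
  }

  if (length(significant) == 0) {
    inform("empty significant set: all pathway p-values set to 1")
    scores <- tibble(pathway = names(paths),
                     size = unname(lengths(paths)),
                     overlap = 0L, expected = 0, p = 1)
    evidence <- tibble(metabolite = reference$metabolites$metabolite, evidence = 0L)
    return(structure(list(scores = scores, evidence = evidence,
                          n_perm = n_perm), class = "pathway_scores"))
  }

  obs <- overlap_of(significant)
  set.seed(derive_seed(seed, 11L))
  null <- matrix(0L, n_perm, length(paths))
  for (b in seq_len(n_perm)) {
    null[b, ] <- overlap_of(sample(all_features, length(significant)))
  }
  p <- (1 + colSums(null >= rep(obs, each = n_perm))) / (n_perm + 1)
  sig_hits <- hits[hits$feature %in% significant, ]
  ev <- sig_hits |>
    distinct(.data$metabolite, .data$feature) |>
    count(.data$metabolite, name = "evidence")
  evidence <- left_join(tibble(metabolite = reference$metabolites$metabolite),
                        ev, by = "metabolite") |>
    mutate(evidence = ifelse(is.na(.data$evidence), 0L, .data$evidence))
  structure(list(
    scores = tibble(pathway = names(paths), size = unname(lengths(paths)),
                    overlap = unname(obs), expected = unname(colMeans(null)),
                    p = unname(p)),
    evidence = evidence, n_perm = n_perm
  ), class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  print(arrange(x$scores, .data$p))
  invisible(x)
}

#' Build the metabolite activity network
#'
#' Retains metabolites that are annotated by at least one significant feature
#' and either reach the evidence cutoff (default 3 distinct supporting
#' significant features) or belong to a pathway scoring below `p_cutoff`.
#' Modules are the connected components of the reference adjacency induced on
#' the retained metabolites.
#'
#' @param hits Annotation from [annotate_mz()].
#' @param scores A [score_pathways()] result.
#' @param reference A [pathway_reference()].
#' @param evidence_cutoff Minimum evidence score for unconditional inclusion.
#' @param p_cutoff Pathway significance level for membership-based inclusion.
#' @return An `activity_network`: `members` (tibble: metabolite, module,
#'   evidence), `graph` (igraph), `n_modules`.
#' @export
build_activity_network <- function(hits, scores, reference,
                                   evidence_cutoff = 3, p_cutoff = 0.05) {
  ev <- scores$evidence
  sig_paths <- scores$scores$pathway[scores$scores$p < p_cutoff]
  in_sig_path <- reference$pathways$metabolite[reference$pathways$pathway %in% sig_paths]
  annotated <- ev$metabolite[ev$evidence > 0]
  keep <- ev$metabolite[(ev$evidence >= evidence_cutoff |
                           ev$metabolite %in% in_sig_path) &
                          ev$metabolite %in% annotated]
  if (length(keep) == 0) {
    return(structure(list(
      members = tibble(metabolite = character(), module = integer(),
                       evidence = integer()),
      graph = igraph::make_empty_graph(), n_modules = 0L
    ), class = "activity_network"))
  }
  g_full <- igraph::graph_from_data_frame(reference$edges, directed = FALSE,
                                          vertices = reference$metabolites$metabolite)
  g <- igraph::induced_subgraph(g_full, keep)
  comp <- igraph::components(g)
  members <- tibble(metabolite = names(comp$membership),
                    module = as.integer(comp$membership)) |>
    left_join(ev, by = "metabolite") |>
    arrange(.data$module, desc(.data$evidence))
  structure(list(members = members, graph = g, n_modules = comp$no),
            class = "activity_network")
}

#' @export
print.activity_network <- function(x, ...) {
  cat(sprintf("Activity network: %d metabolites in %d modules\n",
              nrow(x$members), x$n_modules))
  if (nrow(x$members)) print(x$members)
  invisible(x)
}

#' Merge a second annotated feature list into an activity network input
#'
#' Documented merge used to add a complementary platform (e.g. GC-MS
#' annotations) before network construction: hit lists are concatenated and
#' de-duplicated on (feature, metabolite).
#'
#' @param hits_a,hits_b Annotation tibbles from [annotate_mz()].
#' @export
merge_annotations <- function(hits_a, hits_b) {
  bind_rows(hits_a, hits_b) |>
    distinct(.data$feature, .data$metabolite, .keep_all = TRUE)
}
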