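#' Peptides confidently matched in the collection but missing from the target
#'
#' Starting from scored peptide-spectrum matches against a multi-species
#' proteome collection, keeps peptides that are rank-1 hits with score above
#' the identity threshold; removes any peptide with a target-proteome match
#' of identical score (within `scoreTol`) or an I/L-equivalent target match
#' (isobaric permutations are indistinguishable by MS); and removes peptides
#' whose only above-threshold collection hits lie in excluded databases
#' (e.g. a conspecific strain).
#'
#' @param psmsTarget data.frame of PSMs against the target proteome:
#'   `peptide`, `db_id`, `accession`, `score`, `identity_threshold`, `rank`.
#' @param psmsCollection PSMs against the collection databases, same columns.
#' @param exclusions character vector of `db_id`s whose hits do not count as
#'   collection evidence (default none).
#' @param scoreTol absolute tolerance for the "same score in both databases"
#'   removal (default 0: exact equality).
#' @return data.frame with one row per missing peptide: `peptide`,
#'   `db_ids` (comma-separated collection databases with qualifying hits),
#'   `n_species`, `best_score`.
#' @export
findMissing <- function(psmsTarget, psmsCollection, exclusions = character(0),
                        scoreTol = 0) {
  if (nrow(psmsCollection) == 0)
    return(data.frame(peptide = character(0), db_ids = character(0),
                      n_species = integer(0), best_score = numeric(0)))
  cc <- psmsCollection[psmsCollection$rank == 1 &
                       psmsCollection$score > psmsCollection$identity_threshold, ,
                       drop = FALSE]
  cc <- cc[!(cc$db_id %in% exclusions), , drop = FALSE]
  if (nrow(cc) == 0)
    return(data.frame(peptide = character(0), db_ids = character(0),
                      n_species = integer(0), best_score = numeric(0)))

  tgt_il <- unique(ilCollapseInternal(psmsTarget$peptide))
  drop_il <- ilCollapseInternal(cc$peptide) %in% tgt_il

  same_score <- vapply(seq_len(nrow(cc)), function(i) {
    ts <- psmsTarget$score[psmsTarget$peptide == cc$peptide[i]]
    length(ts) > 0 && any(abs(ts - cc$score[i]) <= scoreTol)
  }, logical(1))

  cc <- cc[!(drop_il | same_score), , drop = FALSE]
  if (nrow(cc) == 0)
    return(data.frame(peptide = character(0), db_ids = character(0),
                      n_species = integer(0), best_score = numeric(0)))
  peps <- sort(unique(cc$peptide))
  data.frame(
    peptide = peps,
    db_ids = vapply(peps, function(p)
      paste(sort(unique(cc$db_id[cc$peptide == p])), collapse = ","),
      character(1)),
    n_species = vapply(peps, function(p)
      length(unique(cc$db_id[cc$peptide == p])), integer(1)),
    best_score = vapply(peps, function(p)
      max(cc$score[cc$peptide == p]), numeric(1)),
    row.names = NULL
  )
}

#' Collapse peptides into containment groups
#'
#' Two peptides belong to the same group when one is a substring of the
#' other under I/L equivalence; the relation is closed transitively
#' (union-find). Each group's representative is its longest member (ties:
#' lexicographically first, flagged).
#'
#' @param peptides character vector of peptide sequences.
#' @param ilEquivalent compare under I/L equivalence (default TRUE); set
#'   FALSE for strict-identity containment.
#' @return data.frame with one row per group: `representative`, `members`
#'   (comma-separated), `n_members`, `tie_flag`.
#' @examples
#' groupContainment(c("ATAQLIESIK", "ATAQLIE", "ATAQL"))  # one group
#' @export
groupContainment <- function(peptides, ilEquivalent = TRUE) {
  peptides <- unique(peptides)
  n <- length(peptides)
  if (n == 0)
    return(data.frame(representative = character(0), members = character(0),
                      n_members = integer(0), tie_flag = logical(0)))
  key <- if (ilEquivalent) ilCollapseInternal(peptides) else peptides

  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- findRoot(i); rj <- findRoot(j); if (ri != rj) parent[ri] <<- rj }

  ord <- order(nchar(key), decreasing = TRUE)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      i <- ord[a]; j <- ord[b]     # key[i] at least as long as key[j]
      if (grepl(key[j], key[i], fixed = TRUE)) union(i, j)
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  groups <- split(seq_len(n), root)
  out <- lapply(groups, function(idx) {
    mem <- peptides[idx]
    lens <- nchar(mem)
    longest <- mem[lens == max(lens)]
    tie <- length(longest) > 1
    data.frame(representative = sort(longest)[1],
               members = paste(sort(mem), collapse = ","),
               n_members = length(mem), tie_flag = tie)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$representative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Taxonomic support summary of missing-peptide groups
#'
#' Counts, per taxonomic group, how many peptide groups have at least one
#' qualifying hit in a database of that taxon. A group counts once per taxon
#' regardless of how many species within the taxon match it; excluded
#' databases (e.g. a conspecific strain) contribute to no taxon.
#'
#' @param groups data.frame from [groupContainment()].
#' @param peptideHits data.frame `peptide`, `db_ids` (comma-separated) from
#'   [findMissing()], mapping member peptides to databases.
#' @param dbTaxonomy data.frame `db_id`, `species`, `taxon_group`.
#' @param exclusions `db_id`s contributing to no taxon.
#' @return named integer vector: groups with >= 1 hit per taxon group.
#' @export
taxonSummary <- function(groups, peptideHits, dbTaxonomy,
                         exclusions = character(0)) {
  taxa <- sort(unique(dbTaxonomy$taxon_group))
  counts <- setNames(integer(length(taxa)), taxa)
  for (g in seq_len(nrow(groups))) {
    members <- strsplit(groups$members[g], ",", fixed = TRUE)[[1]]
    dbs <- unique(unlist(strsplit(
      peptideHits$db_ids[peptideHits$peptide %in% members], ",", fixed = TRUE)))
    dbs <- setdiff(dbs, exclusions)
    if (length(dbs) == 0) next
    unknown <- setdiff(dbs, dbTaxonomy$db_id)
    if (length(unknown))
      stop("unknown db_id in hits: ", paste(unknown, collapse = ", "))
    tg <- unique(dbTaxonomy$taxon_group[dbTaxonomy$db_id %in% dbs])
    counts[tg] <- counts[tg] + 1L
  }
  counts
}
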