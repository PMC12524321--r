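# Pedigree ingestion, consistency QC, recursive ancestor tracing,
# numerator relationship matrix (tabular method) and F_PED.

#' Read a pedigree from delimited text
#'
#' Expects columns `id`, `sire`, `dam`, `sex`, `birth_date` (ISO 8601).
#' Unknown parents may be encoded as an empty field, `"0"` or `NA`.
#'
#' @param path Path to a CSV/TSV file (separator auto-detected).
#' @return A data.frame of raw pedigree rows suitable for
#'   [validate_pedigree()].
#' @export
read_pedigree <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
  df <- as.data.frame(dt, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must contain columns id, sire, dam (found: ",
         paste(names(df), collapse = ", "), ")")
  }
  if (is.null(df$sex)) df$sex <- NA_character_
  if (is.null(df$birth_date)) df$birth_date <- NA_character_
  df[, c("id", "sire", "dam", "sex", "birth_date")]
}

.norm_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

.norm_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male", "1")] <- "male"
  out[x %in% c("f", "female", "2")] <- "female"
  bad <- !is.na(x) & x != "" & x != "0" & x != "unknown" & is.na(out)
  list(sex = ifelse(is.na(out), "unknown", out), invalid = bad)
}

#' Default pedigree QC rule set
#'
#' @param min_parent_age,max_parent_age Plausible window (years) by which a
#'   parent must be older than its offspring; links outside it are severed.
#' @param min_birth_year,max_birth_year Bounds for a realistic birth date.
#' @return A named list of rule parameters for [validate_pedigree()].
#' @export
pedigree_qc_rules <- function(min_parent_age = 2, max_parent_age = 30,
                              min_birth_year = 1900, max_birth_year = 2100) {
  list(min_parent_age = min_parent_age, max_parent_age = max_parent_age,
       min_birth_year = min_birth_year, max_birth_year = max_birth_year)
}

#' Validate and repair a pedigree
#'
#' Applies the consistency checks used when auditing studbook data:
#' duplicated ids, invalid sex codes, animals listed as their own parent,
#' identical sire and dam, parental-sex mismatches, biologically
#' implausible parental ages, and unrealistic or missing birth dates.
#' Offending parent links are severed (set to unknown) rather than rows
#' dropped, except exact duplicate rows which are collapsed. Any cycle that
#' survives the row-level checks is broken by severing the parent link of
#' the cycle member appearing last in input order. Every action is logged.
#'
#' @param records Raw rows as returned by [read_pedigree()], or any
#'   data.frame with columns `id`, `sire`, `dam` and optionally `sex`,
#'   `birth_date`.
#' @param rules Rule parameters from [pedigree_qc_rules()].
#' @return A list with elements `pedigree` (a topologically ordered
#'   `pedigree` data.frame: `id`, `sire`, `dam`, `sex`, `birth_date`) and
#'   `report` (data.frame `id`, `issue`, `detail`, `action`).
#' @export
validate_pedigree <- function(records, rules = pedigree_qc_rules()) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(df$sex)) df$sex <- NA_character_
  if (is.null(df$birth_date)) df$birth_date <- NA_character_
  df$id <- as.character(df$id)
  df$sire <- .norm_parent(df$sire)
  df$dam <- .norm_parent(df$dam)

  issues <- list()
  log_issue <- function(id, issue, detail, action) {
    issues[[length(issues) + 1L]] <<- data.frame(
      id = id, issue = issue, detail = detail, action = action,
      stringsAsFactors = FALSE)
  }

  if (any(is.na(df$id) | df$id == "")) stop("empty animal id in pedigree input")

  ## duplicates: identical rows collapsed; conflicting rows keep the first
  dup <- duplicated(df$id)
  if (any(dup)) {
    for (i in which(dup)) {
      first <- df[match(df$id[i], df$id), ]
      same <- identical(unname(unlist(first)), unname(unlist(df[i, ])))
      log_issue(df$id[i], "duplicate",
                if (same) "identical duplicate row" else "conflicting duplicate row; first kept",
                "row dropped")
    }
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL

  sx <- .norm_sex(df$sex)
  for (i in which(sx$invalid)) {
    log_issue(df$id[i], "invalid-sex", paste0("sex code '", df$sex[i], "'"),
              "sex set unknown")
  }
  df$sex <- sx$sex

  bd <- suppressWarnings(as.Date(df$birth_date))
  for (i in seq_len(nrow(df))) {
    if (is.na(df$birth_date[i])) {
      log_issue(df$id[i], "missing-birth-date", "no birth date", "flagged")
    } else if (is.na(bd[i])) {
      log_issue(df$id[i], "unrealistic-birth-date",
                paste0("unparseable date '", df$birth_date[i], "'"), "date set unknown")
    } else {
      yr <- as.integer(format(bd[i], "%Y"))
      if (yr < rules$min_birth_year || yr > rules$max_birth_year) {
        log_issue(df$id[i], "unrealistic-birth-date",
                  paste0("birth year ", yr), "date set unknown")
        bd[i] <- NA
      }
    }
  }
  df$birth_date <- bd

  ## self-parent
  for (i in seq_len(nrow(df))) {
    if (!is.na(df$sire[i]) && df$sire[i] == df$id[i]) {
      log_issue(df$id[i], "self-parent", "sire equals animal", "sire set unknown")
      df$sire[i] <- NA
    }
    if (!is.na(df$dam[i]) && df$dam[i] == df$id[i]) {
      log_issue(df$id[i], "self-parent", "dam equals animal", "dam set unknown")
      df$dam[i] <- NA
    }
  }

  ## identical sire and dam
  for (i in seq_len(nrow(df))) {
    if (!is.na(df$sire[i]) && !is.na(df$dam[i]) && df$sire[i] == df$dam[i]) {
      log_issue(df$id[i], "sire-equals-dam", paste0("both parents '", df$sire[i], "'"),
                "both links severed")
      df$sire[i] <- NA
      df$dam[i] <- NA
    }
  }

  ## parental sex mismatch: flagged, link kept
  sex_of <- stats::setNames(df$sex, df$id)
  for (i in seq_len(nrow(df))) {
    s <- df$sire[i]; d <- df$dam[i]
    if (!is.na(s) && !is.na(sex_of[s]) && sex_of[s] == "female") {
      log_issue(df$id[i], "parental-sex-mismatch",
                paste0("sire ", s, " recorded female"), "link kept, flagged")
    }
    if (!is.na(d) && !is.na(sex_of[d]) && sex_of[d] == "male") {
      log_issue(df$id[i], "parental-sex-mismatch",
                paste0("dam ", d, " recorded male"), "link kept, flagged")
    }
  }

  ## implausible parental age
  by_year <- function(x) suppressWarnings(as.numeric(format(x, "%Y")) +
                                            (as.numeric(format(x, "%j")) - 1) / 365.25)
  yr <- by_year(df$birth_date)
  names(yr) <- df$id
  for (i in seq_len(nrow(df))) {
    for (side in c("sire", "dam")) {
      p <- df[[side]][i]
      if (is.na(p) || is.na(yr[df$id[i]]) || is.na(yr[p])) next
      gap <- yr[df$id[i]] - yr[p]
      if (gap < rules$min_parent_age || gap > rules$max_parent_age) {
        log_issue(df$id[i], "implausible-parental-age",
                  sprintf("%s %s is %.1f years older", side, p, gap),
                  paste(side, "set unknown"))
        df[[side]][i] <- NA
      }
    }
  }

  ## unresolved parent references become implicit founders
  for (side in c("sire", "dam")) {
    miss <- !is.na(df[[side]]) & !(df[[side]] %in% df$id)
    if (any(miss)) {
      add <- unique(df[[side]][miss])
      df <- rbind(df, data.frame(
        id = add, sire = NA_character_, dam = NA_character_,
        sex = if (side == "sire") "male" else "female",
        birth_date = as.Date(NA), stringsAsFactors = FALSE))
    }
  }

  ## cycle detection: sever the parent link of the latest-input cycle member
  repeat {
    ord <- .toposort(df$id, df$sire, df$dam)
    if (!is.null(ord)) break
    cyc <- .find_cycle(df$id, df$sire, df$dam)
    if (is.null(cyc)) stop("pedigree not orderable but no cycle found (internal error)")
    i <- max(match(cyc, df$id))
    log_issue(df$id[i], "cycle",
              paste0("cycle through ", paste(cyc, collapse = " -> ")),
              "parent links severed")
    if (is.na(df$sire[i]) && is.na(df$dam[i])) {
      stop("unresolvable pedigree cycle involving: ", paste(cyc, collapse = ", "))
    }
    df$sire[i] <- NA
    df$dam[i] <- NA
  }
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")

  report <- if (length(issues)) do.call(rbind, issues) else
    data.frame(id = character(), issue = character(), detail = character(),
               action = character(), stringsAsFactors = FALSE)
  list(pedigree = df, report = report)
}

## Kahn topological sort on parent->offspring edges; NULL if cyclic.
.toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- idx[sire]; di <- idx[dam]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    ## pop the smallest input index for a stable order
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) NULL else out
}

.find_cycle <- function(id, sire, dam) {
  idx <- seq_along(id)
  names(idx) <- id
  parents <- function(i) {
    p <- c(idx[sire[i]], idx[dam[i]])
    p[!is.na(p)]
  }
  state <- integer(length(id)) # 0 unvisited, 1 on stack, 2 done
  stack <- integer(0)
  found <- NULL
  visit <- function(i) {
    if (!is.null(found)) return()
    if (state[i] == 1L) {
      pos <- match(i, stack)
      found <<- id[stack[pos:length(stack)]]
      return()
    }
    if (state[i] == 2L) return()
    state[i] <<- 1L
    stack <<- c(stack, i)
    for (p in parents(i)) visit(p)
    stack <<- stack[-length(stack)]
    state[i] <<- 2L
  }
  for (i in idx) {
    visit(i)
    if (!is.null(found)) return(found)
  }
  NULL
}

.as_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree")) {
    stop("expected a 'pedigree' object; run validate_pedigree() first ",
         "(it also topologically sorts the records)")
  }
  ped
}

#' Extract the sub-pedigree of an individual's ancestors
#'
#' Recursively traces ancestors of `id` up to `max_gen` generations; parents
#' beyond the horizon are set to unknown in the returned records.
#'
#' @param ped A `pedigree` from [validate_pedigree()].
#' @param id Individual id (single string), or a character vector of ids
#'   whose ancestor sets are unioned.
#' @param max_gen Generation horizon (>= 0); 5 matches common studbook
#'   practice.
#' @return A `pedigree` containing the focal individual(s) and their traced
#'   ancestors, topologically ordered.
#' @export
trace_ancestors <- function(ped, id, max_gen = 5) {
  ped <- .as_pedigree(ped)
  stopifnot(max_gen >= 0)
  missing_ids <- setdiff(id, ped$id)
  if (length(missing_ids)) {
    stop("unknown id(s): ", paste(missing_ids, collapse = ", "))
  }
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  gen <- stats::setNames(rep(Inf, nrow(ped)), ped$id)
  frontier <- id
  gen[frontier] <- 0
  g <- 0
  while (length(frontier) && g < max_gen) {
    parents <- unique(stats::na.omit(c(ped$sire[idx[frontier]], ped$dam[idx[frontier]])))
    parents <- parents[gen[parents] > g + 1]
    gen[parents] <- pmin(gen[parents], g + 1)
    frontier <- parents
    g <- g + 1
  }
  keep <- is.finite(gen)
  sub <- ped[keep, , drop = FALSE]
  ## sever links to parents beyond the horizon
  at_edge <- gen[sub$id] >= max_gen
  sub$sire[at_edge] <- NA
  sub$dam[at_edge] <- NA
  sub$sire[!is.na(sub$sire) & !(sub$sire %in% sub$id)] <- NA
  sub$dam[!is.na(sub$dam) & !(sub$dam %in% sub$id)] <- NA
  rownames(sub) <- NULL
  class(sub) <- c("pedigree", "data.frame")
  sub
}

#' Pedigree depth and number of complete generations
#'
#' `depth` is the length of the longest ancestral path; `complete` is the
#' largest g such that all 2^g ancestor slots at generation g are filled.
#'
#' @param ped A `pedigree`.
#' @param id Individual id(s); defaults to all.
#' @return data.frame with columns `id`, `depth`, `complete`.
#' @export
generation_metrics <- function(ped, id = ped$id) {
  ped <- .as_pedigree(ped)
  if (!all(id %in% ped$id)) {
    stop("unknown id(s): ", paste(setdiff(id, ped$id), collapse = ", "))
  }
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]
  depth <- integer(nrow(ped))
  complete <- integer(nrow(ped))
  for (i in seq_len(nrow(ped))) { # topological order: parents precede i
    s <- si[i]; d <- di[i]
    ds <- if (is.na(s)) -1L else depth[s]
    dd <- if (is.na(d)) -1L else depth[d]
    depth[i] <- 1L + max(ds, dd, -1L)
    complete[i] <- if (is.na(s) || is.na(d)) 0L else 1L + min(complete[s], complete[d])
  }
  data.frame(id = id, depth = depth[idx[id]], complete = complete[idx[id]],
             stringsAsFactors = FALSE)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the additive genetic relationship matrix A by the tabular
#' recursion: A_ii = 1 + A_sd / 2 and A_ij = (A_j,sire(i) + A_j,dam(i)) / 2,
#' with unknown parents treated as unrelated non-inbred founders.
#'
#' @param ped A topologically ordered `pedigree`.
#' @return Dense symmetric matrix with individual ids as dimnames.
#' @export
build_a_matrix <- function(ped) {
  ped <- .as_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- idx[ped$sire]; di <- idx[ped$dam]
  if (any(!is.na(si) & si > idx) || any(!is.na(di) & di > idx)) {
    stop("pedigree is not topologically ordered; run validate_pedigree() ",
         "or sort parents before offspring")
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Pedigree inbreeding coefficient F_PED
#'
#' F_PED(i) = A_ii - 1, reported only for individuals with at least
#' `min_complete_generations` complete ancestral generations; others are
#' returned as `NA` (never zero-filled).
#'
#' @param A Relationship matrix from [build_a_matrix()].
#' @param ped The `pedigree` used to build `A` (source of completeness).
#' @param ids Individuals to report; defaults to all in `A`.
#' @param min_complete_generations Completeness filter (default 5).
#' @return data.frame with columns `id`, `f_ped`, `complete`.
#' @export
f_ped <- function(A, ped, ids = rownames(A), min_complete_generations = 5) {
  ped <- .as_pedigree(ped)
  if (!all(ids %in% rownames(A))) {
    stop("ids missing from A: ", paste(setdiff(ids, rownames(A)), collapse = ", "))
  }
  gm <- generation_metrics(ped, ids)
  f <- diag(A)[ids] - 1
  f[gm$complete < min_complete_generations] <- NA_real_
  data.frame(id = ids, f_ped = unname(f), complete = gm$complete,
             stringsAsFactors = FALSE)
}

#' Export a relationship matrix as long-format pairs
#'
#' @param A Matrix from [build_a_matrix()].
#' @param lower_only Emit each unordered pair once (default TRUE).
#' @return data.frame `i`, `j`, `value`.
#' @export
a_matrix_long <- function(A, lower_only = TRUE) {
  ids <- rownames(A)
  idx <- which(if (lower_only) lower.tri(A, diag = TRUE) else matrix(TRUE, nrow(A), ncol(A)),
               arr.ind = TRUE)
  data.frame(i = ids[idx[, 1]], j = ids[idx[, 2]], value = A[idx],
             stringsAsFactors = FALSE)
}
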