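# Triple graph with set semantics, W3C N-Triples/Turtle serialization, and a
# basic-graph-pattern query engine (conjunctive joins only; anything richer
# belongs to a full SPARQL store ingesting the serialized files).

RDF_NAMESPACES <- c(
  rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
  xsd   = "http://www.w3.org/2001/XMLSchema#",
  ro    = "http://www.radiomics.org/RO/",
  roo   = "http://www.cancerdata.org/roo/",
  local = "http://radsem.example.org/local/")

.expand_iri <- function(x) {
  m <- regexpr("^([A-Za-z][A-Za-z0-9]*):(.*)$", x)
  if (m == -1L) return(x)
  parts <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", x))[[1]]
  ns <- RDF_NAMESPACES[parts[2]]
  if (is.na(ns)) return(x)   # already an absolute IRI with unknown scheme
  paste0(ns, parts[3])
}

.compact_iri <- function(iri) {
  for (pfx in names(RDF_NAMESPACES)) {
    ns <- RDF_NAMESPACES[[pfx]]
    if (startsWith(iri, ns)) {
      lp <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z0-9_.-]*$", lp) && !grepl("^[.-]|[.]$", lp))
        return(paste0(pfx, ":", lp))
    }
  }
  paste0("<", iri, ">")
}

#' Construct a triple graph
#'
#' @param s,p,o character vectors: subject IRI, predicate IRI, object
#' @param o_type per-triple object kind: `"iri"`, `"string"` or `"decimal"`
#' @return object of class `triple_graph` (a de-duplicated triple table)
#' @export
triple_graph <- function(s = character(0), p = character(0),
                         o = character(0), o_type = character(0)) {
  df <- data.frame(s = as.character(s), p = as.character(p),
                   o = as.character(o), o_type = as.character(o_type),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("triple_graph", "data.frame")
  df
}

#' @export
print.triple_graph <- function(x, ...) {
  cat(sprintf("<triple_graph> %d triple(s)\n", nrow(x)))
  if (nrow(x) > 0)
    print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Union of triple graphs (set semantics)
#'
#' Merging runs is a plain set union; triples shared between runs collapse,
#' and run-specific nodes (distinct software/settings fingerprints) stay
#' distinct, which is what lets a query separate software implementations in
#' a merged graph.
#'
#' @param ... `triple_graph` objects
#' @return the merged `triple_graph`
#' @export
graph_union <- function(...) {
  gs <- list(...)
  df <- unique(do.call(rbind, lapply(gs, as.data.frame)))
  rownames(df) <- NULL
  class(df) <- c("triple_graph", "data.frame")
  df
}

.fmt_decimal <- function(v) sprintf("%.15g", v)

.slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

#' Build the provenance triple graph for one extraction run
#'
#' The graph encodes, per feature: an `rdf:type` link to its ontology code, a
#' human-readable `rdfs:label`, the value as a typed decimal literal, and the
#' link to its VOI node. The VOI links to the patient node, and every feature
#' links to one shared software node (name, version, programming language)
#' and one shared settings node (discretization, bin width/count, resampling,
#' re-segmentation) — the computation details a consumer can query to explain
#' discordant values between tools. Feature IRIs embed the run fingerprint so
#' two runs with different settings or software never collide.
#'
#' @param features result of [extract_all()]
#' @param patient_id patient identifier (required; the graph links features to
#'   the clinical world through this node)
#' @param voi name of the volume of interest
#' @param cfg the [extraction_config()] used
#' @return a `triple_graph`
#' @export
build_graph <- function(features, patient_id, voi, cfg = extraction_config()) {
  if (is.null(features) || nrow(features) == 0L)
    stop("cannot build a graph from an empty feature list")
  if (is.null(patient_id) || !nzchar(patient_id))
    stop("patient_id is required: the graph would be unlinkable")
  fp <- config_fingerprint(cfg)
  pat <- paste0("local:patient/", .slug(patient_id))
  voi_node <- paste0(pat, "/voi/", .slug(voi))
  sw <- paste0("local:software/", .slug(cfg$software_name), "/",
               .slug(cfg$software_version))
  st <- paste0("local:settings/", fp)

  s <- character(0); p <- character(0); o <- character(0); ot <- character(0)
  add <- function(ss, pp, oo, tt = "iri") {
    s <<- c(s, ss); p <<- c(p, pp); o <<- c(o, oo); ot <<- c(ot, tt)
  }
  add(pat, "roo:hasID", patient_id, "string")
  add(pat, "rdf:type", "roo:Patient")
  add(voi_node, "rdf:type", "ro:VolumeOfInterest")
  add(voi_node, "rdfs:label", voi, "string")
  add(voi_node, "roo:ofPatient", pat)
  add(sw, "rdf:type", "ro:RadiomicsSoftware")
  add(sw, "rdfs:label", cfg$software_name, "string")
  add(sw, "ro:softwareVersion", cfg$software_version, "string")
  add(sw, "ro:programmingLanguage", cfg$software_language, "string")
  add(st, "rdf:type", "ro:ComputationSettings")
  add(st, "ro:discretizationMethod",
      if (!is.null(cfg$bin_count)) "fixed_bin_count" else "fixed_bin_width",
      "string")
  if (!is.null(cfg$bin_width)) add(st, "ro:binWidth", .fmt_decimal(cfg$bin_width), "decimal")
  if (!is.null(cfg$bin_count)) add(st, "ro:binCount", .fmt_decimal(cfg$bin_count), "decimal")
  add(st, "ro:resampledSpacing",
      if (is.null(cfg$resample_spacing)) "none"
      else paste(cfg$resample_spacing, collapse = ","), "string")
  add(st, "ro:resegmentationRange",
      if (is.null(cfg$reseg_range)) "none"
      else paste(cfg$reseg_range, collapse = ","), "string")

  for (i in seq_len(nrow(features))) {
    fnode <- paste0(pat, "/", .slug(voi), "/", fp, "/",
                    .slug(paste(features$family[i], features$name[i])))
    code <- features$ibsi_code[i]
    code_iri <- if (startsWith(code, "local_"))
      paste0("local:feature/", code) else paste0("ro:", code)
    add(fnode, "rdf:type", code_iri)
    add(fnode, "rdfs:label", paste(features$family[i], features$name[i]),
        "string")
    add(fnode, "ro:hasValue", .fmt_decimal(features$value[i]), "decimal")
    add(fnode, "ro:ofVOI", voi_node)
    add(fnode, "ro:computedWith", sw)
    add(fnode, "ro:usedSettings", st)
  }
  iri <- ot == "iri"
  s <- vapply(s, .expand_iri, character(1), USE.NAMES = FALSE)
  p <- vapply(p, .expand_iri, character(1), USE.NAMES = FALSE)
  o[iri] <- vapply(o[iri], .expand_iri, character(1), USE.NAMES = FALSE)
  triple_graph(s, p, o, ifelse(iri, "iri", ifelse(ot == "decimal",
                                                  "decimal", "string")))
}

.escape_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

.unescape_lit <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

.obj_term <- function(o, o_type, compact = FALSE) {
  if (o_type == "iri") {
    if (compact) .compact_iri(o) else paste0("<", o, ">")
  } else if (o_type == "decimal") {
    dt <- paste0(RDF_NAMESPACES[["xsd"]], "double")
    paste0("\"", o, "\"^^", if (compact) .compact_iri(dt)
           else paste0("<", dt, ">"))
  } else {
    paste0("\"", .escape_lit(o), "\"")
  }
}

#' Serialize a triple graph to N-Triples or Turtle
#'
#' Output follows the W3C grammars; parsing the file back yields an equal
#' triple set. Decimal literals carry 15 significant digits.
#'
#' @param g a `triple_graph`
#' @param path output file
#' @param format `"ntriples"` or `"turtle"`
#' @return `path`, invisibly
#' @export
serialize_graph <- function(g, path, format = c("ntriples", "turtle")) {
  format <- match.arg(format)
  if (format == "ntriples") {
    lines <- if (nrow(g) == 0L) character(0) else sprintf(
      "<%s> <%s> %s .", g$s, g$p,
      mapply(.obj_term, g$o, g$o_type, MoreArgs = list(compact = FALSE)))
  } else {
    header <- sprintf("@prefix %s: <%s> .", names(RDF_NAMESPACES),
                      unname(RDF_NAMESPACES))
    body <- if (nrow(g) == 0L) character(0) else sprintf(
      "%s %s %s .",
      vapply(g$s, .compact_iri, character(1)),
      vapply(g$p, .compact_iri, character(1)),
      mapply(.obj_term, g$o, g$o_type, MoreArgs = list(compact = TRUE)))
    lines <- if (length(body) == 0L) character(0) else c(header, "", body)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# tokenize one triple line into subject/predicate/object terms, respecting
# quoted literals
.tokenize_triple <- function(line) {
  toks <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == ".") { i <- i + 1L; next }
    if (ch == "<") {
      j <- regexpr(">", substr(line, i, n), fixed = TRUE)
      toks <- c(toks, substr(line, i, i + j - 1L)); i <- i + j
    } else if (ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(line, j, j)
        if (cj == "\\") j <- j + 2L
        else if (cj == "\"") break
        else j <- j + 1L
      }
      # include optional ^^<datatype> / ^^prefix:name suffix
      k <- j + 1L
      if (substr(line, k, k + 1L) == "^^") {
        k <- k + 2L
        if (substr(line, k, k) == "<") {
          jj <- regexpr(">", substr(line, k, n), fixed = TRUE)
          k <- k + jj
        } else {
          while (k <= n && !substr(line, k, k) %in% c(" ", "\t")) k <- k + 1L
        }
      }
      toks <- c(toks, substr(line, i, k - 1L)); i <- k
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      tok <- substr(line, i, j - 1L)
      if (tok == ".") tok <- NULL
      if (!is.null(tok) && nzchar(tok)) {
        if (endsWith(tok, ".") && !grepl("^\\d", tok))
          tok <- substr(tok, 1, nchar(tok) - 1L)
        toks <- c(toks, tok)
      }
      i <- j
    }
  }
  toks
}

.parse_term <- function(tok, prefixes) {
  if (startsWith(tok, "<")) {
    list(value = substr(tok, 2L, nchar(tok) - 1L), type = "iri")
  } else if (startsWith(tok, "\"")) {
    m <- regexec('^"((?:[^"\\\\]|\\\\.)*)"(\\^\\^(.*))?$', tok)[[1]]
    parts <- regmatches(tok, list(m))[[1]]
    lex <- .unescape_lit(parts[2])
    dt <- parts[4]
    if (nzchar(dt)) {
      dt_iri <- if (startsWith(dt, "<")) substr(dt, 2L, nchar(dt) - 1L)
                else .expand_with(dt, prefixes)
      if (dt_iri %in% paste0(RDF_NAMESPACES[["xsd"]], c("double", "decimal",
                                                        "float", "integer")))
        return(list(value = lex, type = "decimal"))
    }
    list(value = lex, type = "string")
  } else {
    list(value = .expand_with(tok, prefixes), type = "iri")
  }
}

.expand_with <- function(x, prefixes) {
  m <- regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", x)[[1]]
  if (m[1] == -1L) return(x)
  parts <- regmatches(x, list(m))[[1]]
  ns <- prefixes[parts[2]]
  if (is.na(ns)) return(x)
  paste0(unname(ns), parts[3])
}

#' Parse an N-Triples or Turtle file back into a triple graph
#'
#' Supports the subset [serialize_graph()] emits: `@prefix` declarations and
#' one triple per line (no `;`/`,` abbreviations, no blank nodes).
#'
#' @param path file to read
#' @param format `"ntriples"`, `"turtle"`, or `"auto"` (by extension)
#' @return a `triple_graph`
#' @export
parse_graph <- function(path, format = c("auto", "ntriples", "turtle")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ttl$", path)) "turtle" else "ntriples"
  lines <- readLines(path, warn = FALSE)
  prefixes <- character(0)
  s <- character(0); p <- character(0); o <- character(0); ot <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "@prefix")) {
      m <- regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s+<([^>]*)>\\s*\\.$",
                   ln)[[1]]
      parts <- regmatches(ln, list(m))[[1]]
      if (length(parts) == 3L) prefixes[parts[2]] <- parts[3]
      next
    }
    toks <- .tokenize_triple(ln)
    if (length(toks) != 3L)
      stop("malformed triple line (expected 3 terms): ", ln)
    st <- .parse_term(toks[1], prefixes)
    pt <- .parse_term(toks[2], prefixes)
    obj <- .parse_term(toks[3], prefixes)
    s <- c(s, st$value); p <- c(p, pt$value)
    o <- c(o, obj$value); ot <- c(ot, obj$type)
  }
  triple_graph(s, p, o, ot)
}

#' Write features to CSV
#'
#' One row per (patient, VOI, feature); columns `patient_id`, `voi`,
#' `family`, `name`, `ibsi_code`, `value`. Values use the same 15-significant
#' -digit representation as the RDF decimal literals, so the two outputs
#' agree bit for bit.
#'
#' @param features result of [extract_all()] (or several row-bound results)
#' @param patient_id,voi identifiers for the rows (vectorized over features
#'   if given per-row)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
features_to_csv <- function(features, patient_id, voi, path) {
  df <- data.frame(patient_id = patient_id, voi = voi,
                   family = features$family, name = features$name,
                   ibsi_code = features$ibsi_code,
                   value = vapply(features$value, .fmt_decimal, character(1)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Query a triple graph with a basic graph pattern
#'
#' The pattern is a small text syntax: whitespace-separated triple patterns
#' terminated by `.`, with `?var` variables, IRIs in `<>` or prefixed form,
#' and quoted literals — the conjunctive core of SPARQL. Join semantics are
#' exact: a result row satisfies every pattern simultaneously. Output columns
#' follow first appearance of each variable.
#'
#' @param g a `triple_graph`
#' @param pattern query text, e.g.
#'   `"?f rdf:type ro:TU9B . ?f ro:hasValue ?v"`
#' @return data.frame of variable bindings (zero rows if no match)
#' @export
query_graph <- function(g, pattern) {
  chunks <- .split_patterns(pattern)
  if (length(chunks) == 0L) stop("empty query pattern")
  pats <- lapply(chunks, function(ch) {
    toks <- .tokenize_triple(ch)
    if (length(toks) != 3L)
      stop("malformed triple pattern (expected 3 terms): ", ch)
    lapply(toks, function(tok) {
      if (startsWith(tok, "?")) list(var = substring(tok, 2L))
      else .parse_term(tok, RDF_NAMESPACES)
    })
  })
  var_order <- character(0)
  for (pt in pats)
    for (term in pt)
      if (!is.null(term$var) && !term$var %in% var_order)
        var_order <- c(var_order, term$var)

  bind <- NULL   # data.frame of bindings
  for (pt in pats) {
    cand <- as.data.frame(g)[, c("s", "p", "o"), drop = FALSE]
    # filter on constants, then keep variable columns strictly by position so
    # a variable called ?p cannot collide with the predicate column
    keep_pos <- integer(0); keepvars <- character(0)
    for (ti in 1:3) {
      term <- pt[[ti]]
      if (is.null(term$var)) {
        cand <- cand[cand[[ti]] == term$value, , drop = FALSE]
      } else {
        keep_pos <- c(keep_pos, ti)
        keepvars <- c(keepvars, term$var)
      }
    }
    # a pattern like ?x p ?x requires equal bindings
    while (anyDuplicated(keepvars)) {
      d <- which(duplicated(keepvars))[1]
      first <- match(keepvars[d], keepvars)
      cand <- cand[cand[[keep_pos[first]]] == cand[[keep_pos[d]]], ,
                   drop = FALSE]
      keep_pos <- keep_pos[-d]; keepvars <- keepvars[-d]
    }
    cand <- cand[, keep_pos, drop = FALSE]
    names(cand) <- keepvars
    cand <- unique(cand)
    bind <- if (is.null(bind)) cand
            else merge(bind, cand, by = intersect(names(bind), names(cand)),
                       sort = FALSE)
    if (nrow(bind) == 0L) break
  }
  out <- unique(bind[, intersect(var_order, names(bind)), drop = FALSE])
  rownames(out) <- NULL
  out
}

.split_patterns <- function(text) {
  out <- character(0)
  cur <- character(0)
  i <- 1L; n <- nchar(text); buf <- ""
  in_str <- FALSE
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\"" && substr(text, i - 1L, i - 1L) != "\\")
      in_str <- !in_str
    if (ch == "." && !in_str &&
        (i == n || grepl("^[\\s]*$|^\\s", substr(text, i + 1L, i + 1L)) ||
         substr(text, i + 1L, i + 1L) == "\n")) {
      out <- c(out, buf); buf <- ""
    } else buf <- paste0(buf, ch)
    i <- i + 1L
  }
  if (grepl("\\S", buf)) out <- c(out, buf)
  out[grepl("\\S", out)]
}

#' Concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var x + var y + (mean x - mean y)^2)` with
#' population moments — the agreement measure penalizing both correlation
#' loss and location/scale shift. Two constant equal vectors score 1 by
#' convention.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return value in `[-1, 1]`
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(1)
  2 * cxy / den
}
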