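#' The agents' knowledge base
#'
#' Monitoring criteria are defined by domain specialists and coded in XML:
#' per (patient, modality, context) a desired value range (DVR) plus the two
#' anomaly rules labelling values below and above it, and a routing table
#' mapping anomaly labels to health providers and channels. The schema is
#'
#' ```
#' <knowledgeBase version="1" author="...">
#'   <contexts><context name="icu"/></contexts>            <!-- optional -->
#'   <patients>
#'     <patient id="default">
#'       <sensor modality="body_temperature" unit="C" context="default">
#'         <dvr low="36.0" high="36.6"/>
#'         <anomaly side="below_low"  label="Hypothermia"/>
#'         <anomaly side="above_high" label="Hyperthermia"/>
#'       </sensor>
#'     </patient>
#'   </patients>
#'   <routes>
#'     <route label="Hyperthermia" provider="nurse-1" channel="console"
#'            address="stdout"/>
#'   </routes>
#'   <unrouted><label name="..."/></unrouted>              <!-- optional -->
#'   <assignments><assignment patient="p1" context="icu"/></assignments>
#' </knowledgeBase>
#' ```
#'
#' Validation is eager and exhaustive: every violation is collected and
#' reported at load time, so configuration mistakes surface before any
#' monitoring starts. External entities are never resolved.
#'
#' @name knowledge_base
NULL

kb_key <- function(patient_id, modality, context) {
  paste(patient_id, modality, context, sep = "|")
}

#' Construct a knowledge base in memory
#'
#' @param entries list of entries, each as produced by [kb_entry()].
#' @param routes data frame with columns `label`, `provider_id`, `channel`,
#'   `address` (zero rows allowed).
#' @param unrouted character vector of labels explicitly marked as having no
#'   route (an acknowledged alerting gap, as opposed to a forgotten one).
#' @param contexts character vector of declared context keys; `"default"` is
#'   always known. Context keys used by entries are added automatically.
#' @param assignments named character vector mapping patient ids to their
#'   current context key.
#' @param version,author metadata strings.
#' @return a validated `knowledge_base` object.
#' @export
knowledge_base <- function(entries = list(), routes = empty_routes(),
                           unrouted = character(), contexts = character(),
                           assignments = character(), version = "1",
                           author = "") {
  kb <- structure(list(entries = list(), routes = routes,
                       unrouted = unrouted,
                       contexts = union("default", contexts),
                       assignments = assignments,
                       version = version, author = author),
                  class = "knowledge_base")
  for (e in entries) {
    key <- kb_key(e$patient_id, e$modality, e$context)
    if (!is.null(kb$entries[[key]]))
      stop("conflict: duplicate knowledge-base entry for (",
           e$patient_id, ", ", e$modality, ", ", e$context, ")",
           call. = FALSE)
    kb$entries[[key]] <- e
    kb$contexts <- union(kb$contexts, e$context)
  }
  errs <- kb_violations(kb)
  if (length(errs))
    stop("invalid knowledge base:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  kb
}

empty_routes <- function() {
  data.frame(label = character(), provider_id = character(),
             channel = character(), address = character(),
             stringsAsFactors = FALSE)
}

#' One monitoring entry: a DVR plus its two anomaly rules
#'
#' @param patient_id patient key or `"default"`.
#' @param modality sensor modality.
#' @param low,high DVR bounds (inclusive).
#' @param below_label label raised for values strictly below `low`.
#' @param above_label label raised for values strictly above `high`; must
#'   differ from `below_label`.
#' @param context context key, `"default"` if unspecified.
#' @return an entry list for [knowledge_base()].
#' @export
kb_entry <- function(patient_id, modality, low, high,
                     below_label, above_label, context = "default") {
  d <- dvr(low, high, modality, patient_id, context)
  if (identical(below_label, above_label))
    stop("the two anomaly labels on one DVR must be distinct", call. = FALSE)
  list(patient_id = patient_id, modality = modality, context = context,
       dvr = d,
       rules = list(below_low = anomaly_rule("below_low", below_label),
                    above_high = anomaly_rule("above_high", above_label)))
}

# collect every invariant violation (not just the first)
kb_violations <- function(kb) {
  errs <- character()
  labels <- unlist(lapply(kb$entries, function(e)
    c(e$rules$below_low$label, e$rules$above_high$label)))
  routed <- unique(kb$routes$label)
  for (lab in unique(labels)) {
    if (!(lab %in% routed) && !(lab %in% kb$unrouted))
      errs <- c(errs, paste0("label '", lab,
                             "' has no notification route and is not ",
                             "marked unrouted"))
  }
  if (nrow(kb$routes)) {
    if (!all(kb$routes$channel %in% CHANNELS))
      errs <- c(errs, paste0("unknown channel(s): ",
                             paste(setdiff(kb$routes$channel, CHANNELS),
                                   collapse = ", ")))
    dup <- duplicated(kb$routes[c("label", "provider_id")])
    if (any(dup))
      errs <- c(errs, paste0("duplicate route for (label, provider): ",
                             paste(unique(paste0(kb$routes$label[dup], "/",
                                                 kb$routes$provider_id[dup])),
                                   collapse = ", ")))
  }
  bad_ctx <- setdiff(unname(kb$assignments), kb$contexts)
  if (length(bad_ctx))
    errs <- c(errs, paste0("patient assigned to unknown context(s): ",
                           paste(bad_ctx, collapse = ", ")))
  errs
}

#' Load and validate an XML knowledge base
#'
#' Parses the schema documented in [knowledge_base], collecting every schema
#' violation before failing. A JSON mirror of the same structure is accepted
#' when the file extension is `.json`.
#'
#' @param path path to the XML (or JSON) knowledge-base file.
#' @return a validated `knowledge_base`.
#' @export
load_knowledge_base <- function(path) {
  if (!file.exists(path))
    stop("knowledge-base file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(kb_from_json(path))
  doc <- xml2::read_xml(path, options = c("NOENT", "NONET")[2])
  root <- xml2::xml_name(doc)
  if (root != "knowledgeBase")
    stop("validation error:\n  - root element must be <knowledgeBase>, got <",
         root, ">", call. = FALSE)
  errs <- character()
  entries <- list()
  seen_keys <- character()

  for (pat in xml2::xml_find_all(doc, "./patients/patient")) {
    pid <- xml2::xml_attr(pat, "id")
    if (is.na(pid) || !nzchar(pid)) {
      errs <- c(errs, "<patient> without id attribute")
      next
    }
    for (sensor in xml2::xml_find_all(pat, "./sensor")) {
      modality <- xml2::xml_attr(sensor, "modality")
      context <- xml2::xml_attr(sensor, "context")
      if (is.na(context)) context <- "default"
      where <- paste0("patient '", pid, "' sensor '", modality, "'")
      if (is.na(modality) || !(modality %in% names(MODALITIES))) {
        errs <- c(errs, paste0(where, ": unknown modality"))
        next
      }
      unit <- xml2::xml_attr(sensor, "unit")
      canon <- MODALITIES[[modality]]
      if (!is.na(unit) && !(unit %in% c(canon, "°C")))
        errs <- c(errs, paste0(where, ": unit '", unit, "' does not match ",
                               "modality unit '", canon, "'"))
      dn <- xml2::xml_find_all(sensor, "./dvr")
      if (length(dn) != 1) {
        errs <- c(errs, paste0(where, ": expected exactly one <dvr>"))
        next
      }
      low <- suppressWarnings(as.numeric(xml2::xml_attr(dn, "low")))
      high <- suppressWarnings(as.numeric(xml2::xml_attr(dn, "high")))
      if (is.na(low) || is.na(high)) {
        errs <- c(errs, paste0(where, ": <dvr> low/high must be numeric"))
        next
      }
      if (low > high) {
        errs <- c(errs, paste0(where, ": DVR low > high"))
        next
      }
      an <- xml2::xml_find_all(sensor, "./anomaly")
      sides <- xml2::xml_attr(an, "side")
      labs <- xml2::xml_attr(an, "label")
      if (length(an) != 2 || !setequal(sides, c("below_low", "above_high"))) {
        errs <- c(errs, paste0(where, ": need exactly one below_low and one ",
                               "above_high <anomaly> rule"))
        next
      }
      if (any(is.na(labs)) || any(!nzchar(labs)) ||
          labs[1] == labs[2]) {
        errs <- c(errs, paste0(where, ": anomaly labels must be non-empty ",
                               "and distinct"))
        next
      }
      key <- kb_key(pid, modality, context)
      if (key %in% seen_keys) {
        errs <- c(errs, paste0("conflict: duplicate entry for (", pid, ", ",
                               modality, ", ", context, ")"))
        next
      }
      seen_keys <- c(seen_keys, key)
      entries[[length(entries) + 1L]] <-
        kb_entry(pid, modality, low, high,
                 below_label = labs[sides == "below_low"],
                 above_label = labs[sides == "above_high"],
                 context = context)
    }
  }

  rn <- xml2::xml_find_all(doc, "./routes/route")
  routes <- data.frame(label = xml2::xml_attr(rn, "label"),
                       provider_id = xml2::xml_attr(rn, "provider"),
                       channel = xml2::xml_attr(rn, "channel"),
                       address = xml2::xml_attr(rn, "address"),
                       stringsAsFactors = FALSE)
  routes$address[is.na(routes$address)] <- ""
  if (nrow(routes) && any(is.na(routes$label) | is.na(routes$provider_id) |
                          is.na(routes$channel)))
    errs <- c(errs, "<route> requires label, provider and channel attributes")

  unrouted <- xml2::xml_attr(xml2::xml_find_all(doc, "./unrouted/label"),
                             "name")
  contexts <- xml2::xml_attr(xml2::xml_find_all(doc, "./contexts/context"),
                             "name")
  asg_nodes <- xml2::xml_find_all(doc, "./assignments/assignment")
  assignments <- stats::setNames(xml2::xml_attr(asg_nodes, "context"),
                                 xml2::xml_attr(asg_nodes, "patient"))

  if (length(errs))
    stop("validation error:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)

  version <- xml2::xml_attr(doc, "version")
  author <- xml2::xml_attr(doc, "author")
  knowledge_base(entries, routes, unrouted = unrouted[!is.na(unrouted)],
                 contexts = contexts[!is.na(contexts)],
                 assignments = assignments,
                 version = if (is.na(version)) "1" else version,
                 author = if (is.na(author)) "" else author)
}

kb_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(j$entries, function(e)
    kb_entry(e$patient_id, e$modality, e$low, e$high,
             e$below_label, e$above_label,
             context = if (is.null(e$context)) "default" else e$context))
  routes <- if (length(j$routes)) {
    do.call(rbind, lapply(j$routes, function(r)
      data.frame(label = r$label, provider_id = r$provider_id,
                 channel = r$channel,
                 address = if (is.null(r$address)) "" else r$address,
                 stringsAsFactors = FALSE)))
  } else empty_routes()
  knowledge_base(entries, routes,
                 unrouted = as.character(unlist(j$unrouted)),
                 contexts = as.character(unlist(j$contexts)),
                 assignments = unlist(j$assignments) %||% character(),
                 version = j$version %||% "1", author = j$author %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a knowledge base to XML
#'
#' The written file satisfies `load_knowledge_base(save_knowledge_base(kb))
#' == kb` field for field. An invalid knowledge base (e.g. one with a label
#' that is neither routed nor marked unrouted) is refused.
#'
#' @param kb a `knowledge_base`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_knowledge_base <- function(kb, path) {
  errs <- kb_violations(kb)
  if (length(errs))
    stop("refusing to save invalid knowledge base:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  doc <- xml2::xml_new_root("knowledgeBase", version = kb$version,
                            author = kb$author)
  if (length(setdiff(kb$contexts, "default"))) {
    cn <- xml2::xml_add_child(doc, "contexts")
    for (ctx in setdiff(kb$contexts, "default"))
      xml2::xml_add_child(cn, "context", name = ctx)
  }
  pn <- xml2::xml_add_child(doc, "patients")
  by_patient <- split(kb$entries,
                      vapply(kb$entries, function(e) e$patient_id,
                             character(1)))
  for (pid in names(by_patient)) {
    pat <- xml2::xml_add_child(pn, "patient", id = pid)
    for (e in by_patient[[pid]]) {
      sn <- xml2::xml_add_child(pat, "sensor", modality = e$modality,
                                unit = MODALITIES[[e$modality]],
                                context = e$context)
      xml2::xml_add_child(sn, "dvr",
                          low = format(e$dvr$low, digits = 15),
                          high = format(e$dvr$high, digits = 15))
      xml2::xml_add_child(sn, "anomaly", side = "below_low",
                          label = e$rules$below_low$label)
      xml2::xml_add_child(sn, "anomaly", side = "above_high",
                          label = e$rules$above_high$label)
    }
  }
  rn <- xml2::xml_add_child(doc, "routes")
  if (nrow(kb$routes)) {
    for (i in seq_len(nrow(kb$routes)))
      xml2::xml_add_child(rn, "route", label = kb$routes$label[i],
                          provider = kb$routes$provider_id[i],
                          channel = kb$routes$channel[i],
                          address = kb$routes$address[i])
  }
  if (length(kb$unrouted)) {
    un <- xml2::xml_add_child(doc, "unrouted")
    for (lab in kb$unrouted) xml2::xml_add_child(un, "label", name = lab)
  }
  if (length(kb$assignments)) {
    an <- xml2::xml_add_child(doc, "assignments")
    for (pid in names(kb$assignments))
      xml2::xml_add_child(an, "assignment", patient = pid,
                          context = kb$assignments[[pid]])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Resolve the effective DVR and rules for a patient
#'
#' Normal ranges are defined per patient and sensor, with modality-level
#' defaults. Resolution is deterministic, most specific first:
#' (patient, context) > (patient, default) > (default, context) >
#' (default, default).
#'
#' @param kb a `knowledge_base`.
#' @param patient_id patient key.
#' @param modality sensor modality.
#' @param context context key; if `NULL`, the patient's current assignment
#'   in the knowledge base (or `"default"`) is used.
#' @return a list with elements `dvr` and `rules`.
#' @export
effective_rules <- function(kb, patient_id, modality, context = NULL) {
  if (is.null(context))
    context <- patient_context(kb, patient_id)
  candidates <- c(kb_key(patient_id, modality, context),
                  kb_key(patient_id, modality, "default"),
                  kb_key("default", modality, context),
                  kb_key("default", modality, "default"))
  for (key in unique(candidates)) {
    e <- kb$entries[[key]]
    if (!is.null(e)) return(list(dvr = e$dvr, rules = e$rules))
  }
  stop("configuration missing: no monitoring entry for (",
       patient_id, ", ", modality, ") in context '", context, "'",
       call. = FALSE)
}

#' Current context assignment of a patient
#' @param kb a `knowledge_base`.
#' @param patient_id patient key.
#' @return context key string (`"default"` if unassigned).
#' @export
patient_context <- function(kb, patient_id) {
  ctx <- kb$assignments[patient_id]
  if (length(ctx) == 0 || is.na(ctx)) "default" else unname(ctx)
}

#' All anomaly labels configured in a knowledge base
#' @param kb a `knowledge_base`.
#' @return character vector of distinct labels.
#' @export
kb_labels <- function(kb) {
  unique(unlist(lapply(kb$entries, function(e)
    c(e$rules$below_low$label, e$rules$above_high$label))))
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base v%s: %d entr%s, %d route%s, %d unrouted>\n",
              x$version, length(x$entries),
              if (length(x$entries) == 1) "y" else "ies",
              nrow(x$routes), if (nrow(x$routes) == 1) "" else "s",
              length(x$unrouted)))
  invisible(x)
}

#' Structural equality of two knowledge bases
#' @param a,b `knowledge_base` objects.
#' @return logical.
#' @export
kb_equal <- function(a, b) {
  norm <- function(kb) {
    kb$entries <- kb$entries[order(names(kb$entries))]
    kb$routes <- kb$routes[order(kb$routes$label, kb$routes$provider_id), ,
                           drop = FALSE]
    rownames(kb$routes) <- NULL
    kb$unrouted <- sort(kb$unrouted)
    kb$contexts <- sort(kb$contexts)
    kb$assignments <- if (length(kb$assignments))
      kb$assignments[order(names(kb$assignments))] else character()
    kb
  }
  isTRUE(all.equal(norm(a), norm(b), check.attributes = FALSE))
}
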