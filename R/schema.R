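#' Define a slot of a template
#'
#' A slot is a named field of a template. It is filled either with free text
#' extracted from the source document (`kind = "textual"`) or with one or more
#' nested instances of other templates (`kind = "template"`).
#'
#' @param name Slot name; an identifier without whitespace or the characters
#'   `[`, `]`, `:`.
#' @param kind `"textual"` or `"template"`.
#' @param templates Character vector of template names allowed as fillers;
#'   required (non-empty) exactly when `kind = "template"`.
#' @param min,max Multiplicity bounds on the number of fillers. `max = Inf`
#'   means unbounded.
#' @return An object of class `slot_def`.
#' @export
#' @examples
#' slot_def("Drug")
#' slot_def("hasMedication", "template", templates = "Medication", max = 1)
slot_def <- function(name, kind = c("textual", "template"), templates = character(),
                     min = 0, max = Inf) {
  kind <- match.arg(kind)
  if (!is_string(name) || !grepl("^[^]\\[:\\s]+$", name, perl = TRUE)) {
    stopf("invalid slot name: %s", deparse(name))
  }
  if (!is_count(min) || !(is_count(max) || identical(max, Inf))) {
    stopf("slot '%s': min/max must be non-negative integers (max may be Inf)", name)
  }
  if (min > max) stopf("slot '%s': min_count > max_count", name)
  templates <- as.character(templates)
  if (kind == "template" && length(templates) == 0L) {
    stopf("slot '%s': kind 'template' requires a non-empty 'templates' set", name)
  }
  if (kind == "textual" && length(templates) > 0L) {
    stopf("slot '%s': kind 'textual' must not list allowed templates", name)
  }
  structure(list(name = name, kind = kind, templates = templates,
                 min = as.integer(min), max = as.numeric(max)),
            class = "slot_def")
}

#' Define a template schema
#'
#' A schema declares a set of templates, each an ordered collection of slots,
#' plus a distinguished root template. Within every template the slots are kept
#' in canonical order: case-sensitive lexicographic (byte) order on slot names,
#' the fixed order that linearization enforces.
#'
#' @param templates Named list mapping template name to a list of [slot_def()]s.
#' @param root Name of the root template.
#' @return A validated object of class `template_schema`.
#' @export
#' @examples
#' sch <- template_schema(
#'   list(Trial = list(slot_def("Country"), slot_def("Title", max = 1))),
#'   root = "Trial"
#' )
template_schema <- function(templates, root) {
  if (!is.list(templates) || is.null(names(templates)) || any(names(templates) == "")) {
    stopf("'templates' must be a named list of slot lists")
  }
  tnames <- names(templates)
  if (anyDuplicated(tnames)) stopf("duplicate template names: %s",
                                   paste(unique(tnames[duplicated(tnames)]), collapse = ", "))
  bad <- tnames[!grepl("^[^]\\[:\\s]+$", tnames, perl = TRUE)]
  if (length(bad)) stopf("invalid template name(s): %s", paste(bad, collapse = ", "))
  templates <- lapply(templates, function(slots) {
    slots <- lapply(slots, function(s) {
      if (!inherits(s, "slot_def")) stopf("every slot must be a slot_def")
      s
    })
    snames <- vapply(slots, `[[`, "", "name")
    if (anyDuplicated(snames)) {
      stopf("duplicate slot names within a template: %s",
            paste(unique(snames[duplicated(snames)]), collapse = ", "))
    }
    slots[order(match(snames, sort_c(snames)))]
  })
  if (!is_string(root) || !root %in% tnames) {
    stopf("root must name a defined template (got %s)", deparse(root))
  }
  sch <- structure(list(root = root, templates = templates), class = "template_schema")
  validate_schema(sch)
  sch
}

#' Validate a template schema
#'
#' Checks referential integrity: every template-typed slot must reference
#' templates defined in the schema, names must be unique, and the root must be
#' defined. Called by the constructors; exported for checking hand-built or
#' loaded schemas.
#'
#' @param schema A `template_schema`.
#' @return The schema, invisibly; errors otherwise.
#' @export
validate_schema <- function(schema) {
  if (!inherits(schema, "template_schema")) stopf("not a template_schema")
  tnames <- names(schema$templates)
  for (tn in tnames) {
    for (s in schema$templates[[tn]]) {
      if (s$kind == "template") {
        missing <- setdiff(s$templates, tnames)
        if (length(missing)) {
          stopf("template '%s', slot '%s': dangling template reference(s): %s",
                tn, s$name, paste(missing, collapse = ", "),
                class = "gcdecode_schema_error")
        }
      }
    }
  }
  invisible(schema)
}

#' @export
print.template_schema <- function(x, ...) {
  cat(sprintf("<template_schema> %d templates, root: %s\n",
              length(x$templates), x$root))
  for (tn in names(x$templates)) {
    slots <- x$templates[[tn]]
    kinds <- vapply(slots, function(s) {
      if (s$kind == "textual") s$name else paste0(s$name, "<", paste(s$templates, collapse = "|"), ">")
    }, "")
    cat(sprintf("  %s: %s\n", tn, paste(kinds, collapse = ", ")))
  }
  invisible(x)
}

#' Slot definitions of a template
#' @param schema A `template_schema`.
#' @param template Template name.
#' @return List of `slot_def`s in canonical order.
#' @export
template_slots <- function(schema, template) {
  slots <- schema$templates[[template]]
  if (is.null(slots)) stopf("unknown template '%s'", template)
  slots
}

# Look up one slot_def (NULL if absent).
find_slot <- function(schema, template, slot) {
  for (s in schema$templates[[template]]) if (s$name == slot) return(s)
  NULL
}

#' All slot names declared in a schema
#'
#' @param schema A `template_schema`.
#' @param kind Optional filter: `"textual"` or `"template"`.
#' @return Character vector of unique slot names, byte-sorted.
#' @export
schema_slot_names <- function(schema, kind = NULL) {
  out <- character()
  for (slots in schema$templates) {
    for (s in slots) {
      if (is.null(kind) || s$kind == kind) out <- c(out, s$name)
    }
  }
  sort_c(unique(out))
}

#' Load a template schema from a JSON file
#'
#' The file dialect is a single JSON object
#' `{"root": name, "templates": {name: [slotdef, ...]}}` where each slotdef is
#' `{"name": string, "kind": "textual"|"template", "templates": [names],
#' "min": int, "max": int|null}`. `kind` defaults to `"textual"`, `min` to 0 and
#' `max` (absent or `null`) to unbounded. Slots are put in canonical order on
#' load regardless of file order.
#'
#' @param path Path to the JSON schema file.
#' @return A validated `template_schema`.
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stopf("schema file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stopf("malformed schema file %s: %s", path, conditionMessage(e)))
  if (is.null(doc$root) || is.null(doc$templates)) {
    stopf("schema file must contain 'root' and 'templates'")
  }
  templates <- lapply(doc$templates, function(slots) {
    lapply(slots, function(sd) {
      slot_def(
        name = sd$name,
        kind = if (is.null(sd$kind)) "textual" else sd$kind,
        templates = if (is.null(sd$templates)) character() else unlist(sd$templates),
        min = if (is.null(sd$min)) 0 else sd$min,
        max = if (is.null(sd$max)) Inf else sd$max
      )
    })
  })
  template_schema(templates, root = doc$root)
}

#' Write a template schema to a JSON file
#'
#' Inverse of [load_schema()]; unbounded `max` is written as `null`.
#'
#' @param schema A `template_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  doc <- list(
    root = schema$root,
    templates = lapply(schema$templates, function(slots) {
      lapply(slots, function(s) {
        list(name = s$name, kind = s$kind,
             templates = I(s$templates),
             min = s$min,
             max = if (is.infinite(s$max)) NULL else as.integer(s$max))
      })
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}
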