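---
title: "Methods: ODM validation, descriptive statistics and completeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ODM validation, descriptive statistics and completeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odminsight)
```

This vignette documents the model behind the package: what is computed,
under which assumptions, which choices were open and how they were made,
and what the synthetic fixtures do and do not establish.

## The data model

A CDISC ODM file carries two halves of one study. The metadata half
defines the CRF structure: study events contain forms, forms contain item
groups, groups contain items; items carry a data type and optionally a
code list. Every definition has a locally unique OID and is *referenced*
into place, so one definition can appear in several arms of the
hierarchy (but at most once inside a given parent — a duplicate reference
is rejected as a structural error). The clinical half mirrors that
hierarchy per subject and references each level by OID; repeating
elements are discriminated by repeat keys, which are opaque strings with
no assumed ordering.

All analysis is **positional**: the unit is one placement of a
definition, identified by the OID path from the study event down. A form
referenced under two events yields two independent sets of statistics.
Names are display metadata only; identity is the OID path. Repeat keys
live on instances, never in metadata paths.

Internally the clinical data is held as one table per level (instance =
row, keyed by subject, OID path and accumulated repeat keys) rather than
as a nested forest; this is the natural R representation and makes the
counting operations single `tapply`/`table` passes.

## Two-stage validation

*Structural* validation checks the document against an explicit grammar
of the supported ODM subset: allowed elements and their nesting order,
required attributes, attribute lexical forms (e.g. `Mandatory` ∈
{Yes, No}, known `DataType` names), and the absence of any element or
attribute outside the ODM namespace. It is implemented as a grammar
table rather than delegating to a schema engine so that every finding
carries an XPath and a reproducible message. Any structural finding
aborts the analysis — parsing cannot be trusted past it. UTF-8 is
required; other declared encodings are rejected.

*Content* validation never aborts. Each instance path is resolved against
the positional tree; an unresolvable instance produces one
`UNDEFINED_REFERENCE` record and its whole subtree is excluded (one
cause, one row — descendants are not reported separately). Each present
item value must convert to its declared type, and, when a code list is
attached, match a coded value exactly. The order is conversion first,
then membership: a value that fails both is reported as `TYPE_MISMATCH`.
Conversion rules follow the XML Schema lexical spaces: booleans accept
exactly `true`/`false`/`1`/`0` (case-sensitive); integers are
optional-sign digit strings; float/double accept decimal notation with
an optional exponent; date/time/datetime accept ISO 8601 forms, with
timezone designators on datetimes accepted and normalized to a UTC
instant so that ordering is total. Values are never trimmed or
case-folded — trimming would silently alter data that is elsewhere
compared byte-for-byte. An `ItemData` whose value attribute is absent or
empty is a *missing* value: an instance without a value, neither valid
nor invalid. ODM types outside the supported set (partial dates and
similar) mark their items `UNSUPPORTED_TYPE`; such items stay visible in
the report but carry no summary.

Statistics and completeness both run on the cleaned dataset, so a
type-invalid value counts as absent downstream. The alternative —
"present but incomplete" — is defensible, but a single consistent
behavior was preferred over a switch; the invalid-value warning flag on
every affected element keeps the exclusions visible.

## Descriptive statistics

Items are categorized on the Stevens scale extended with a dichotomous
class; a code list always wins over its base type, because the list
defines the value space regardless of how codes are spelled.

Choices that the category summaries embody:

* **All values are used.** With repeat keys one subject can contribute
  several values. Averaging per subject first would be wrong for scores
  tracked over visits; taking "the last" is impossible since repeat keys
  are unordered strings. So every value counts and the element is
  flagged, leaving interpretation to the reader.
* **Nominal**: top three byte-exact strings, no normalization, no chart
  (the value space is unbounded). Diversity is the number of distinct
  cleaned values.
* **Ordinal**: per-option counts; diversity reported as observed/total.
  The bar chart shows all options (list order, zero counts included)
  when the list has at most ten, otherwise the top nine by count plus an
  `others` bar summing the remainder — appended last even if it is
  larger than the ninth bar (no re-ranking).
* **Interval**: only the chronological range; a mean of dates of birth
  carries no insight. The distribution is shown as a histogram over a
  numeric encoding (days since epoch for dates, seconds since midnight
  for times, seconds since epoch for datetimes).
* **Ratio**: min, max, mean, median and standard deviation on doubles.
  The median of an even count is the mean of the two central order
  statistics. The standard deviation uses the sample (n−1) denominator —
  the clinical-reporting default — with the n = 1 case defined as 0 so
  the report never prints an undefined value.
* **Ties** in top-k lists break by count descending, then value
  ascending in code-point order, so reports are identical across runs
  and platforms.

Histograms use equal-width bins spanning exactly `[min, max]`; the
default bin count is 10 (matching the bar-chart width cap,
CLI-configurable via `--bins`). Bin membership is decided by comparing
against the emitted borders (last bin closed on both sides), not by
`floor((x - min)/width)`: the two disagree on values that land exactly
on a border after floating-point division, and only the former can be
reproduced by a consumer holding the reported borders. A degenerate
range (all values equal) yields one bin. Borders are reported as doubles
even for integer items.

Counts render as integers; ratio summaries render at one decimal; the
JSON report always carries full precision.

## Completeness

An item instance is complete iff it has a non-empty value. A non-leaf
instance is complete iff (a) every child element mandatory under the
chosen mode has at least one instance inside it and (b) every present
child instance — mandatory or not — is itself complete. The same rule
applied to study events defines a complete subject. For element C under
parent P, `expected(C)` adds to the observed instances one slot for each
P instance lacking any C (only when C is mandatory under the mode), and
the percentage is `100·completed/expected`, undefined (rendered `n/a`,
never 100%) when nothing was expected.

The `mandatory_flag` mode reads flags from the reference that placed the
child — positional, like everything else. The `all_mandatory` mode
treats every element as mandatory; it is monotone against the first mode
(never more completed, never fewer expected), which the test suite
asserts node by node, and it overstates incompleteness for genuinely
optional or conditional items — that is the price of not trusting the
flags.

## The synthetic world

No public ODM study exports exist, so everything is tested against a
deterministic generator whose manifest is computed directly from the
generator's own records — independently of the parser, validator and
statistics code it is used to check (completeness ground truth comes
from a separate recursive oracle over the nested records; summary ground
truth from brute-force recomputation on the manifest's value multisets).

The generator's default world, chosen once: 20 subjects, 2 study events
× 2 forms × 2 item groups × 4 items drawn from all supported types,
code lists of 4 options, a 90% chance that a subject instantiates each
event/form/group, 10% missing values (half as empty-value tags, half as
absent tags — both must behave identically), one repeating group per
form with a 20% repeat chance of up to 3 instances, and mandatory flags
on half of all references. These are plausible magnitudes for a small
registry CRF; nothing in the acceptance criteria depends on them beyond
"structure, repetition, missingness and errors all occur". Error
injection is explicit: a requested number of `TYPE_MISMATCH`,
`NOT_IN_CODELIST`, `UNDEFINED_REFERENCE` and `UNSUPPORTED_TYPE` faults
at random eligible locations, recorded in a ledger that the pipeline
must reproduce exactly.

What a green suite establishes: on files with this structure the
pipeline recovers the generator's ground truth exactly — counts,
multisets, summaries, completeness in both modes, injected errors per
reason and location. What it does not establish: behavior on vendor
extensions, administrative/audit data, transaction semantics
(`TransactionType` is deliberately ignored), multi-megabyte exports, or
ODM 2.0 — all outside scope.

## Numerical and degenerate-input choices

* Empty dataset / never-referenced element: counts (0, 0), summary
  "No data", no chart; completeness percentage `n/a` when expected = 0.
* One value: min = max = mean = median, sd = 0 by convention; histogram
  of one bin.
* Multiple `Study` or `MetaDataVersion` elements: the first is used and
  a warning is recorded; `ClinicalData` blocks for other studies are
  skipped with a warning.
* The JSON report is serialized compactly with full numeric precision;
  the same analysis always produces byte-identical output, and
  write→read→write reproduces the bytes exactly.
* The paginated document is rendered as single-file HTML (one section
  per item, metadata order). The contract is the content, not the
  container; a PDF engine is deliberately not a dependency.

## Known limitations

Partial dates and the other rarer ODM value types are reported as
unsupported rather than analyzed. `ItemGroupDef Repeating="No"` is not
enforced against repeat keys in the data (the standard describes the
discriminator; enforcement is a linting concern and is only surfaced via
the repeat-key warning). Bivariate statistics are out of scope by
design. Parsing is DOM-based via libxml2: memory scales with the file,
which is adequate for the file sizes this package targets but would need
a streaming backend for multi-hundred-megabyte exports.
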