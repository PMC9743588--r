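---
title: "From a relational diagnostics database to a property-graph cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a relational diagnostics database to a property-graph cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical genomic-diagnostics databases are normalized relational schemas:
patients, orders, typed analyses (RNA-seq, panel sequencing, array-CGH),
materials, and key-value result rows are spread over a dozen tables linked by
foreign keys. Questions a cohort researcher actually asks — *which patients
carry the CRLF2-P2RY8 fusion? who resembles this patient? how are ages
distributed by gender?* — require multi-table joins whose results repeat each
patient once per joined combination. A labeled property graph answers the same
questions by traversal, returns each node once, and makes gene-fusion
stratification a one-hop neighborhood.

`rel2graph` implements the full route from one representation to the other:

1. a declarative description of the relational schema,
2. a deterministic rewrite of that schema into a property-graph model,
3. configurable use-case refinements of the model,
4. migration of relational instance data into the graph,
5. the cohort analytics the resulting graph is for, and
6. a seeded synthetic cohort generator so that everything is testable without
   access to clinical data.

## The schema-graph rewrite

The transformation operates on an intermediate *schema graph*: one node per
attribute `R.a` of every relation, with composite primary keys merged into a
single `R.PK` node (and composite foreign keys likewise). Directed edges run
from each PK node to the non-key attributes of its relation and from each FK
node to the referenced PK node. Three degree classes drive the rewrite:
a **sink** has no outgoing edges, a **source** no incoming edges, and a
**hub** both.

The steps, each a fixpoint on its own output:

* **Sink merge.** All plain-attribute sinks hanging off the same PK node with
  one incoming edge merge into a single `R.attributes` node (a single sink is
  relabeled — a merge of one).
* **Entity fusion.** A PK hub with exactly one outgoing edge to a merged sink
  fuses with it into an entity node labeled `R`. Hubs whose merged sink has
  further incoming edges are left untouched and reported rather than guessed
  at.
* **Source resolution.** A source linked by FK edges to exactly two entities
  becomes an undirected relationship edge. An additional edge to a merged
  sink turns the sink's attributes into relationship properties (an order
  date travels on the ordering edge, not on a node). An additional edge to an
  FK hub whose only other edge reaches an otherwise-unreferenced entity with
  a single data attribute pulls that attribute in as a lookup property and
  removes hub and entity — this is how an optional diagnosis addition's
  description ends up on the diagnosis edge.
* **FK-hub resolution.** A remaining FK node between two entities becomes a
  relationship edge. A source PK node with one FK edge and one merged sink —
  the key-value field table — first fuses into a new entity (its FK attribute
  is consumed by the edge), then connects to its host.

Anything the steps cannot classify (n-ary associations, isolated relations)
is kept as an entity, with one relationship per remaining FK; ternary
associations genuinely cannot be expressed as a single binary edge.

**Conservation.** Every `(relation, attribute)` pair of the input schema is
recorded in a placement ledger: entity key, entity property, relationship
property, FK consumed by an edge, or lookup key consumed by absorption.
`model_audit()` verifies each attribute is placed exactly once; the test
suite enforces this on randomly generated schemas.

**Determinism and naming.** All candidate iteration is in lexicographic label
order, so the derived model is independent of declaration order. Relationship
names carry domain meaning that no mechanical rule recovers (an edge derived
from `Analysis.order_id` reads best as `HasAnalysis` when traversed from the
order), so names come from an explicit `name_map` keyed by origin relation or
`Relation.fk_column`; the fallbacks are `Has<Target>` for FK-derived edges,
`Has<NewEntity>` for edges created together with a new entity, and the
association name for source-derived edges. The shipped map reproduces the
reference diagnostics model exactly.

**Stored direction.** The model's edges are conceptually undirected, but a
property-graph store needs a stored direction. FK-derived edges point from
the FK-owning entity to the referenced entity. For association-derived edges
the FK declaration order of the associative relation decides (first declared
FK = source endpoint); the shipped schema declares the patient-side FK first,
so edges read `Patient -[HasOrder]-> Order`. Analytics treat all edges as
undirected, so this choice never affects results.

## Use-case refinements

Three rewrites adapt the mechanical model to the dashboard use case, driven
by the shipped `default_config.yaml`:

* `absorb_entity(AnalysisMaster -> Analysis, mode = "subtype_labels")` — the
  master table holds nothing but an id and a type, so each distinct type value
  becomes an extra node label (`RNASeqAnalysis`, `PanelAnalysis`,
  `ArrayCGHAnalysis`) and analyses stay queryable both generically and by
  assay. Labels are flat; deeper assay taxonomies would fit the same
  mechanism but none is defined. The alternative `mode = "attribute"` stores
  the type as a property instead.
* `merge_hierarchy(MaterialNumber -> Material, "CreatedFrom")` — sub-materials
  become `Material` nodes with optional `sub_type`/`sub_number` properties
  and a `CreatedFrom` self-relationship to their main material. Materials are
  deliberately *not* subtyped by label: with over fifty material types that
  would inflate the label set without aiding queries.
* `promote_dynamic_field` — key-value result rows are a placeholder for
  assay-specific results. A field with a huge numeric domain (the measurement
  `q`) becomes a property on its analysis. Fields naming fusions or
  aneuploidies become shared `Fusion` nodes reached by `HasFusion`: equal
  (canonicalized) values map to one node, so patients with the same
  aberration meet at the same node regardless of which assay detected it.
  Which fields to promote, and in which mode, is a config decision — the
  choice depends on domain knowledge about the field's value set, not on
  anything inferable from the schema.

In the field table, `field` is the per-analysis storage slot (part of the
primary key) while `name` carries the semantic key; promotion rules match on
`name`, which is what lets one analysis report several fusions.

Aneuploidies are encoded in the same feature namespace as fusions, as
canonical tokens `ANEUPLOIDY:<TYPE>` in the shipped catalog. One namespace
means one node identity rule, one subgroup selector and one similarity
feature space for both kinds of aberration.

## Migration

`migrate()` creates one node per row of each entity-origin relation with
identity `label:PK`, so re-running the migration merges instead of
duplicating; the Cypher export consists of `MERGE` statements keyed the same
way and replays idempotently. Nulls are omitted rather than stored. Fusion
values are canonicalized (trim, uppercase, alias lookup through the catalog)
before node identity, so `p2ry8-crlf2` and `CRLF2-P2RY8` meet at one node.
Conflicting property values under one identity key raise an error rather than
silently keeping one side; with `skip_violations = TRUE` referentially broken
rows are dropped, cascading to their dependents, and reported.

After the material hierarchy merge, main materials and sub-materials share
the `Material` label, so their source id spaces must not collide; the
synthetic generator keeps them in disjoint ranges, and a real deployment
would ensure the same before merging.

`validate_migration()` checks the losslessness contract: per-label node
counts equal source row counts (distinct canonical values for promoted
entities), edge counts equal source rows or non-null FK values, and every
associative table reconstructs set-exactly from the edges.

## Analytics

* `distribution()` cross-tabulates a per-patient selector against an optional
  grouping selector, zero cells included. Ages are completed calendar years
  (floor), binned at `bin_width` (default 1 year, matching per-year dashboard
  bars); current age needs an explicit `reference_date` — there is no hidden
  "today". A patient with several values (two diagnoses, three materials)
  counts once per value; `measure = "frequency"` therefore normalizes by the
  table total so frequencies always sum to 1.
* `feature_set()` is the union of canonical fusion names, aneuploidy tokens
  and diagnosis ICD codes; duplicate detections collapse.
* `jaccard()` is the plain cardinality ratio `|A ∩ B| / |A ∪ B|`. Two empty
  sets score 0 by convention: sharing no recorded features is not evidence of
  similarity, and the convention avoids 0/0.
* `similarity_graph()` keeps candidates whose score strictly *exceeds* the
  threshold (default 0.2, configurable — a convention, not a calibrated
  value), so a threshold of 0 still excludes entirely dissimilar patients.
  Edge sets are antitone in the threshold.
* `subgroup()` resolves aliases through the catalog, returns the carriers
  with per-patient columns (age, karyotype-related values where measured) and
  a display subgraph, optionally expanded by node types such as `Material`.
  A catalog-known name with no detections yields an empty table and a
  one-node subgraph rather than an error.
* `patient_subgraph()` expands breadth-first through the requested labels
  only, and never *through* cohort-shared nodes (fusions, diagnoses,
  projects, families): without that rule a shared fusion node would pull the
  records of every other carrier into an "individual" view.
* `dedup_query()` matches an alternating label/type path pattern and returns
  the union subgraph of complete matches — each node once, however many paths
  cross it; the tests pit it against the equivalent relational join, which
  repeats each patient per (analysis, result) combination.

## The synthetic cohort

The generator emulates the *structure* of the source database, not its
clinical joint distributions. Defaults: even gender split; 10% non-ALL
cases (AML, MDS, Trisomy 21); per-fusion carrier prevalences from the shipped
catalog (ETV6-RUNX1 0.22, high hyperdiploidy 0.25, CRLF2-P2RY8 0.08, ... —
plausible magnitudes for B-ALL subgroups, chosen once and documented as
scale parameters, not clinical claims); about 1.3 orders and 2-3 analyses
per patient with an RNA-seq/panel/array-CGH mix of 50/30/20; one or two
materials per patient, each with at least one sub-material; pediatric birth
dates (2004-2020) and diagnosis dates after birth. Carriers are guaranteed a
detecting assay (RNA-seq for fusions, array-CGH for aneuploidies), and 30%
of detections are written using an alias spelling to exercise resolution.

Each fusion is an independent Bernoulli draw per patient, which is what makes
carrier counts binomially testable; the per-patient fusion-count distribution
is consequently emergent rather than a parameter. Fusion co-occurrence,
genotype-phenotype correlation, survival and treatment are all absent — a
passing suite shows the pipeline is correct, not that the data are clinically
realistic.

All sampling flows from one seeded stream; the same seed reproduces the CSVs
byte for byte. Ground truth (who carries what, per-patient tallies) is
written alongside the instance for tests only — the pipeline never reads it.

## Problem sizes and numerical choices

The test suite exercises cohorts of 100 and 500 patients (about 6,400 nodes
and 9,200 edges at 500) and recovers generator prevalences over ten seeded
replicates of 500 patients, pooling counts per fusion across replicates and
checking them against three-sigma binomial envelopes — pooling keeps the
simultaneous-test count at nine instead of ninety, so a correct generator is
not rejected by multiplicity. Dates are ISO-8601 throughout; CSV nulls are
empty cells; all tie-breaks in the rewrite are lexicographic. A larger,
study-scale preset is just `cohort_params(n_patients = 2185)`.

## Known limitations

* Mixed FKs (part of the primary key, part not) are rejected rather than
  transformed.
* A PK hub whose merged sink has other incoming edges is reported and kept,
  not rewritten; no input exercising this case has a published answer.
* Only full re-migration is supported; change-data-capture is out of scope,
  idempotent `MERGE` semantics being the substitute.
* Jaccard over fusions, aneuploidies and diagnosis codes is the only
  similarity measure; richer measures (age, karyotype, symptoms) would slot
  into `feature_set()` but are not implemented.
* The alias catalog is a configurable fixture with no claim of clinical
  completeness.
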