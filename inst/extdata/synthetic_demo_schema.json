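[
  {
    "name": "pnom1",
    "level": "person",
    "kind": "nominal",
    "categories": ["c1", "c2", "c3"],
    "reference": "c1"
  },
  {
    "name": "pnom2",
    "level": "person",
    "kind": "nominal",
    "categories": ["c1", "c2"],
    "reference": "c1"
  },
  {
    "name": "pnom3",
    "level": "person",
    "kind": "nominal",
    "categories": ["c1", "c2"],
    "reference": "c1"
  },
  {
    "name": "pnom4",
    "level": "person",
    "kind": "nominal",
    "categories": ["c1", "c2", "c3"],
    "reference": "c1"
  },
  {
    "name": "pcon1",
    "level": "person",
    "kind": "continuous"
  },
  {
    "name": "pcon2",
    "level": "person",
    "kind": "continuous"
  },
  {
    "name": "pcon3",
    "level": "person",
    "kind": "continuous"
  },
  {
    "name": "pcon4",
    "level": "person",
    "kind": "continuous"
  },
  {
    "name": "pcon5",
    "level": "person",
    "kind": "continuous"
  },
  {
    "name": "pcon6",
    "level": "person",
    "kind": "continuous"
  },
  {
    "name": "pcon7",
    "level": "person",
    "kind": "continuous"
  },
  {
    "name": "pcon8",
    "level": "person",
    "kind": "continuous"
  },
  {
    "name": "pcon9",
    "level": "person",
    "kind": "continuous"
  },
  {
    "name": "inom1",
    "level": "item",
    "kind": "nominal",
    "categories": ["c1", "c2"],
    "reference": "c1"
  },
  {
    "name": "inom2",
    "level": "item",
    "kind": "nominal",
    "categories": ["c1", "c2"],
    "reference": "c1"
  },
  {
    "name": "inom3",
    "level": "item",
    "kind": "nominal",
    "categories": ["c1", "c2", "c3"],
    "reference": "c1"
  }
]
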