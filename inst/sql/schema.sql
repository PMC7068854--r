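-- Relational schema for pre-processed protein-ligand structural data.
-- Denormalized on purpose: distance tables repeat residue/ligand codes and
-- sequence indexes so pattern queries avoid extra joins.

CREATE TABLE protein (
  id             TEXT PRIMARY KEY,      -- 4-character PDB code
  chain          TEXT NOT NULL,         -- selected (largest) chain
  classification TEXT,
  organism       TEXT
);

CREATE TABLE standard_amino (
  name     TEXT PRIMARY KEY,            -- 20 standard names + 'undefined'
  polarity TEXT
);

CREATE TABLE amino (
  id         TEXT PRIMARY KEY,          -- "<pdb>_<chain>_<seq_index>"
  protein_id TEXT    NOT NULL REFERENCES protein(id),
  seq_index  INTEGER NOT NULL,
  name3      TEXT    NOT NULL,
  std_name   TEXT    NOT NULL REFERENCES standard_amino(name)
);

CREATE TABLE ligand (
  id         TEXT PRIMARY KEY,          -- "<pdb>_<chain>_L<ordinal>"
  protein_id TEXT NOT NULL REFERENCES protein(id),
  code       TEXT NOT NULL
);

CREATE TABLE atom_amino (
  id       TEXT PRIMARY KEY,            -- "<amino_id>_<atom_ordinal>"
  amino_id TEXT    NOT NULL REFERENCES amino(id),
  serial   INTEGER NOT NULL,
  element  TEXT,
  x REAL NOT NULL, y REAL NOT NULL, z REAL NOT NULL
);

CREATE TABLE atom_ligand (
  id        TEXT PRIMARY KEY,
  ligand_id TEXT    NOT NULL REFERENCES ligand(id),
  serial    INTEGER NOT NULL,
  element   TEXT,
  x REAL NOT NULL, y REAL NOT NULL, z REAL NOT NULL
);

-- minimum atom-pair distances <= 7.0 A, one row per unordered residue
-- pair (lower seq_index first)
CREATE TABLE distance_amino_amino (
  protein_id TEXT    NOT NULL REFERENCES protein(id),
  amino1_id  TEXT    NOT NULL REFERENCES amino(id),
  amino2_id  TEXT    NOT NULL REFERENCES amino(id),
  name1      TEXT    NOT NULL,
  name2      TEXT    NOT NULL,
  seq1       INTEGER NOT NULL,
  seq2       INTEGER NOT NULL,
  distance   REAL    NOT NULL,
  PRIMARY KEY (amino1_id, amino2_id)
);

CREATE TABLE distance_ligand_amino (
  protein_id  TEXT    NOT NULL REFERENCES protein(id),
  ligand_id   TEXT    NOT NULL REFERENCES ligand(id),
  amino_id    TEXT    NOT NULL REFERENCES amino(id),
  ligand_code TEXT    NOT NULL,
  amino_name  TEXT    NOT NULL,
  seq         INTEGER NOT NULL,
  distance    REAL    NOT NULL,
  PRIMARY KEY (ligand_id, amino_id)
);

CREATE TABLE next_amino_amino (
  protein_id TEXT NOT NULL REFERENCES protein(id),
  amino1_id  TEXT NOT NULL REFERENCES amino(id),
  amino2_id  TEXT NOT NULL REFERENCES amino(id),
  PRIMARY KEY (amino1_id, amino2_id)
);

CREATE TABLE protein_cath (
  protein_id TEXT NOT NULL REFERENCES protein(id),
  cath_code  TEXT NOT NULL,
  PRIMARY KEY (protein_id, cath_code)
);

CREATE INDEX idx_amino_protein_name ON amino(protein_id, name3);
CREATE INDEX idx_amino_protein_std  ON amino(protein_id, std_name);
CREATE INDEX idx_amino_protein_seq  ON amino(protein_id, seq_index);
CREATE INDEX idx_ligand_protein_code ON ligand(protein_id, code);
CREATE INDEX idx_daa_a1      ON distance_amino_amino(amino1_id);
CREATE INDEX idx_daa_a2      ON distance_amino_amino(amino2_id);
CREATE INDEX idx_daa_protein ON distance_amino_amino(protein_id);
CREATE INDEX idx_dla_lig     ON distance_ligand_amino(ligand_id);
CREATE INDEX idx_dla_amino   ON distance_ligand_amino(amino_id);
CREATE INDEX idx_dla_protein ON distance_ligand_amino(protein_id);
CREATE INDEX idx_next_a1     ON next_amino_amino(amino1_id);
CREATE INDEX idx_next_protein ON next_amino_amino(protein_id);
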