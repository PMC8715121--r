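# Scheme configuration schema

Kinetic schemes and their rate constants are declared in YAML.  All
concentrations in trace files and configs are micromolar; rate constants are
`/s` (unimolecular) or `/uM/s` (bimolecular).  `/mM/s` and `/nM/s` are
accepted on input and converted on load.

## Blocks

### `name` (string, required)

Scheme identifier.

### `states` (list of strings, required)

Unique state names, in pathway order.  The first state is the reference
(free enzyme-DNA) state.

### `ligands` (list of strings, optional)

Free-species names.  A transition direction that references a ligand is
bimolecular.

### `transitions` (list, required)

Each entry:

| field        | required | meaning                                          |
|--------------|----------|--------------------------------------------------|
| `from`, `to` | yes      | declared state names                             |
| `k_fwd`      | yes      | forward rate-constant (parameter name)           |
| `k_rev`      | no       | reverse rate-constant; absent = irreversible     |
| `ligand`     | no       | ligand consumed in the forward direction         |
| `ligand_rev` | no       | ligand consumed in the reverse direction         |

### `parameters` (mapping, required)

One entry per rate constant named in the transitions:

| field        | required | meaning                                          |
|--------------|----------|--------------------------------------------------|
| `value`      | yes      | strictly positive number                         |
| `units`      | no       | `/s` (default), `/uM/s`, `/mM/s`, `/nM/s`        |
| `locked`     | no       | `true` to hold fixed during fitting              |
| `bounds`     | no       | `[low, high]` box constraints                    |
| `link_group` | no       | label; same-label parameters are fitted as one   |

## Example

```yaml
name: two_step_binding
states: [ED, EDT, FDT]
ligands: [dTTP]
transitions:
  - {from: ED,  to: EDT, k_fwd: kB1, k_rev: kmB1, ligand: dTTP}
  - {from: EDT, to: FDT, k_fwd: kB2, k_rev: kmB2}
parameters:
  kB1:  {value: 10, units: /uM/s, locked: true}
  kmB1: {value: 15000}
  kB2:  {value: 310}
  kmB2: {value: 6.8}
```
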