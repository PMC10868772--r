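species,morphotype
Passiflora coriacea,A
Passiflora misera,A
Passiflora biflora,B
Passiflora capsularis,B
Passiflora micropetala,B
Passiflora organensis,B
Passiflora pohlii,B
Passiflora rubra,B
Passiflora tricuspis,B
Passiflora caerulea,C
Passiflora cincinnata,C
Passiflora edmundoi,C
Passiflora gibertii,C
Passiflora hatschbachii,C
Passiflora kermesina,C
Passiflora mollissima,C
Passiflora setacea,C
Passiflora suberosa,C
Passiflora tenuifila,C
Passiflora amethystina,D
Passiflora foetida,D
Passiflora gracilis,D
Passiflora morifolia,D
Passiflora actinia,E
Passiflora miersii,E
Passiflora sidifolia,E
Passiflora triloba,E
Passiflora alata,F
Passiflora edulis,F
Passiflora ligularis,F
Passiflora nitida,F
Passiflora racemosa,F
Passiflora villosa,F
Passiflora coccinea,G
Passiflora cristalina,G
Passiflora galbana,G
Passiflora malacophylla,G
Passiflora maliformis,G
Passiflora miniata,G
Passiflora mucronata,G
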