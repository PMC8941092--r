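source_label,cover_class
Evergreen Forest,coniferous
Deciduous Forest,broadleaf
Mixed Forest,broadleaf
Woodland,coniferous
Low Shrub,shrub_herbaceous
Tall Shrub,shrub_herbaceous
Open Shrubs,shrub_herbaceous
Herbaceous,shrub_herbaceous
Tussock Tundra,shrub_herbaceous
Sparsely Vegetated,barren_sparse
Barren,barren_sparse
Fen,wetland
Bog,wetland
Shallows/Littoral,wetland
Water,wetland
coniferous,coniferous
broadleaf,broadleaf
shrub_herbaceous,shrub_herbaceous
barren_sparse,barren_sparse
wetland,wetland
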