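data_calcite_r3c
_cell_length_a    4.989600
_cell_length_b    4.989600
_cell_length_c    17.061000
_cell_angle_alpha 90.000000
_cell_angle_beta  90.000000
_cell_angle_gamma 120.000000
_symmetry_space_group_name_H-M 'R-3c'
loop_
_symmetry_equiv_pos_as_xyz
'x,y,z'
'-y,x-y,z'
'-x+y,-x,z'
'y,x,-z+1/2'
'x-y,-y,-z+1/2'
'-x,-x+y,-z+1/2'
'-x,-y,-z'
'y,-x+y,-z'
'x-y,x,-z'
'-y,-x,z+1/2'
'-x+y,y,z+1/2'
'x,x-y,z+1/2'
'x+2/3,y+1/3,z+1/3'
'-y+2/3,x-y+1/3,z+1/3'
'-x+y+2/3,-x+1/3,z+1/3'
'y+2/3,x+1/3,-z+5/6'
'x-y+2/3,-y+1/3,-z+5/6'
'-x+2/3,-x+y+1/3,-z+5/6'
'-x+2/3,-y+1/3,-z+1/3'
'y+2/3,-x+y+1/3,-z+1/3'
'x-y+2/3,x+1/3,-z+1/3'
'-y+2/3,-x+1/3,z+5/6'
'-x+y+2/3,y+1/3,z+5/6'
'x+2/3,x-y+1/3,z+5/6'
'x+1/3,y+2/3,z+2/3'
'-y+1/3,x-y+2/3,z+2/3'
'-x+y+1/3,-x+2/3,z+2/3'
'y+1/3,x+2/3,-z+1/6'
'x-y+1/3,-y+2/3,-z+1/6'
'-x+1/3,-x+y+2/3,-z+1/6'
'-x+1/3,-y+2/3,-z+2/3'
'y+1/3,-x+y+2/3,-z+2/3'
'x-y+1/3,x+2/3,-z+2/3'
'-y+1/3,-x+2/3,z+1/6'
'-x+y+1/3,y+2/3,z+1/6'
'x+1/3,x-y+2/3,z+1/6'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
_atom_site_occupancy
_atom_site_B_iso_or_equiv
Ca1 Ca 0.000000000 0.000000000 0.000000000 1.000000 0.000000
C2 C 0.000000000 0.000000000 0.250000000 1.000000 0.000000
O3 O 0.256700000 0.000000000 0.250000000 1.000000 0.000000
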