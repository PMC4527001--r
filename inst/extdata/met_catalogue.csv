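item_id,label,domain,met
work_sedentary,sedentary work,daily occupation,1.3
work_light,light work,daily occupation,2
work_moderate,moderate work,daily occupation,3.5
work_heavy,heavy manual work,daily occupation,6.5
transport_walk,walking to work,transportation,3.5
transport_bicycle,bicycling to work,transportation,6.8
transport_car,driving to work,transportation,1.3
walking_leisure,leisure walking,leisure,3
household_work,household work,leisure,2.8
gardening,gardening,leisure,3.8
yoga,yoga,leisure,2.5
swimming,swimming laps,sport,7
bicycling,bicycling,sport,7.5
spinning,spinning class,sport,8.5
skiing,cross-country skiing,sport,9
squash,squash,sport,9.5
running,running,sport,8
sitting_leisure,sitting during leisure,leisure,1.3
sleep,sleep,sleep,0.95
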