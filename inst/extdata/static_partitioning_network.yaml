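components:
- name: activator
  radius: 0
  count: 10
  mobility: 0.1
  initial_state: 'on'
  states:
  - name: 'on'
    boundary_pref: -1
- name: inactivator
  radius: 0
  count: 10
  mobility: 0.1
  initial_state: 'on'
  states:
  - name: 'on'
    boundary_pref: 1
- name: target
  radius: 0
  count: 20
  mobility: 0.1
  initial_state: inactive
  states:
  - name: inactive
    boundary_pref: 1
  - name: active
    boundary_pref: 1
rules:
- actor: activator
  actor_state: 'on'
  substrate: target
  substrate_state: inactive
  product_state: active
  rate: 1.0
  activity_sign: 1
- actor: inactivator
  actor_state: 'on'
  substrate: target
  substrate_state: active
  product_state: inactive
  rate: 1.0
  activity_sign: -1
target: target
active_state: active
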