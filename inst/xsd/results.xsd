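<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <!-- Result documents: one object element per (possibly suffixed)
       identifier, one measurement element per scored variable. Every
       measurement is tagged with its entity and attribute term ids, so
       parsing is independent of element order and the variable set may
       differ between objects without placeholder entries. -->

  <xs:simpleType name="nonempty">
    <xs:restriction base="xs:string">
      <xs:minLength value="1"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="datatype">
    <xs:restriction base="xs:string">
      <xs:enumeration value="numeric"/>
      <xs:enumeration value="categorical"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="phenotyping_results">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="object" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="measurement" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="entity" type="nonempty" use="required"/>
                  <xs:attribute name="attribute" type="nonempty" use="required"/>
                  <xs:attribute name="datatype" type="datatype" use="required"/>
                  <xs:attribute name="value" type="nonempty" use="required"/>
                  <xs:attribute name="unit" type="xs:string"/>
                  <xs:attribute name="timestamp" type="nonempty" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="id" type="nonempty" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="scheme" type="xs:string"/>
      <xs:attribute name="device" type="nonempty" use="required"/>
      <xs:attribute name="started" type="nonempty" use="required"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
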